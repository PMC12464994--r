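# Peak assignment tables: expected chemical shifts per species, search
# windows, and the overlap structure (which species are fitted as one
# component because their peaks are unresolved).

FD_SPECIES <- c("A_2F", "B_2F", "A_1F", "B_1F")

#' Build a peak assignment table
#'
#' An assignment table names, for each dimer species signal, the expected
#' chemical shift and a search half-window, and groups species whose peaks
#' overlap so tightly that they must be deconvolved as a single component.
#' Species naming follows the field convention: `A_2F`/`B_2F` are the two
#' monomer signals of a doubly labeled homodimer; `A_1F`/`B_1F` are the
#' single labeled monomer of a heterodimer sitting in position A or B.
#'
#' @param centers named numeric vector of expected chemical shifts (ppm) for
#'   the four species `A_2F`, `B_2F`, `A_1F`, `B_1F`.
#' @param half_window search half-window in ppm around each expected center
#'   (scalar or named vector). Fitted centers are bounded to
#'   `center +/- half_window`.
#' @param overlap_groups list of character vectors partitioning the species
#'   into groups fitted as one Lorentzian each. Default: every species in
#'   its own singleton group (fully resolved).
#' @return An object of class `"assignment_table"`.
#' @seealso [assignment_preset()] for the experimentally observed layouts.
#' @export
assignment_table <- function(centers,
                             half_window = 0.3,
                             overlap_groups = NULL) {
  stopifnot(is.numeric(centers))
  if (!setequal(names(centers), FD_SPECIES)) {
    stop("centers must be named for exactly the species: ",
         paste(FD_SPECIES, collapse = ", "), call. = FALSE)
  }
  centers <- centers[FD_SPECIES]
  if (any(!is.finite(centers))) stop("centers must be finite", call. = FALSE)
  if (length(half_window) == 1L) {
    half_window <- setNames(rep(half_window, 4L), FD_SPECIES)
  } else {
    stopifnot(setequal(names(half_window), FD_SPECIES))
    half_window <- half_window[FD_SPECIES]
  }
  if (any(half_window <= 0)) {
    stop("half_window must be positive (non-degenerate windows)",
         call. = FALSE)
  }
  if (is.null(overlap_groups)) overlap_groups <- as.list(FD_SPECIES)
  members <- unlist(overlap_groups)
  if (!setequal(members, FD_SPECIES) || anyDuplicated(members)) {
    stop("overlap_groups must partition the species (each in exactly one ",
         "group)", call. = FALSE)
  }
  overlap_groups <- lapply(overlap_groups, function(g) {
    FD_SPECIES[FD_SPECIES %in% g]
  })
  structure(
    list(centers = centers, half_window = half_window,
         overlap_groups = overlap_groups),
    class = "assignment_table"
  )
}

#' @export
print.assignment_table <- function(x, ...) {
  cat("<assignment_table>\n")
  for (s in FD_SPECIES) {
    cat(sprintf("  %-4s %8.2f ppm  +/- %.2f\n",
                s, x$centers[[s]], x$half_window[[s]]))
  }
  groups <- vapply(x$overlap_groups, paste, "", collapse = "+")
  cat("  overlap groups:", paste(groups, collapse = ", "), "\n")
  invisible(x)
}

#' Named assignment presets for the measured sample types
#'
#' Chemical-shift layouts observed for 5-fluoro-tryptophan-labeled EmrE
#' samples in isotropic bicelles at pH 5.6:
#' \describe{
#'   \item{`"5FW-W63"`}{doubly labeled homodimer peaks at -124.8 (A) and
#'     -123.2 ppm (B); heterodimer A at -125.4 ppm; heterodimer B at
#'     -123.3 ppm, unresolved from the homodimer B peak (fitted as one
#'     merged B component).}
#'   \item{`"5FW-W63-L51I"`}{as above with the L51I-context heterodimer A
#'     signal at -125.1 ppm; the B region is again merged.}
#'   \item{`"5FW-W63-E14Q"`}{the E14Q-context heterodimer B signal is
#'     shifted to -122.0 ppm and resolved, so all four species are fitted
#'     separately.}
#'   \item{`"6FW-W63"`}{6-fluoro-tryptophan layout. The experimental 6FW
#'     shifts are not published; these centers are synthetic stand-ins for
#'     simulation work only.}
#' }
#'
#' @param name preset name.
#' @return An [assignment_table()].
#' @export
assignment_preset <- function(name = c("5FW-W63", "5FW-W63-L51I",
                                       "5FW-W63-E14Q", "6FW-W63")) {
  name <- match.arg(name)
  switch(name,
    "5FW-W63" = assignment_table(
      c(A_2F = -124.8, B_2F = -123.2, A_1F = -125.4, B_1F = -123.3),
      overlap_groups = list("A_2F", "A_1F", c("B_2F", "B_1F"))
    ),
    "5FW-W63-L51I" = assignment_table(
      c(A_2F = -124.8, B_2F = -123.2, A_1F = -125.1, B_1F = -123.3),
      half_window = c(A_2F = 0.3, B_2F = 0.3, A_1F = 0.14, B_1F = 0.3),
      overlap_groups = list("A_2F", "A_1F", c("B_2F", "B_1F"))
    ),
    "5FW-W63-E14Q" = assignment_table(
      c(A_2F = -124.8, B_2F = -123.2, A_1F = -125.4, B_1F = -122.0)
    ),
    # synthetic: 6FW shifts are not published
    "6FW-W63" = assignment_table(
      c(A_2F = -122.5, B_2F = -124.0, A_1F = -124.6, B_1F = -122.6),
      half_window = 0.04
    )
  )
}

# Does the table resolve B_1F from B_2F (the E14Q-style layout)?
b1f_resolved <- function(table) {
  for (g in table$overlap_groups) {
    if ("B_1F" %in% g) return(length(g) == 1L)
  }
  FALSE
}
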