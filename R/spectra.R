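# Forward spectrum model: area-parameterized Lorentzians whose areas follow
# the species-mixing and Boltzmann-population model, plus Gaussian noise;
# text-based spectrum I/O.

#' Construct a 1D spectrum object
#'
#' @param axis chemical-shift grid in ppm, strictly monotone, length >= 64.
#'   Stored ascending internally; a descending input is reversed and the
#'   flip recorded in `metadata$axis_was_descending`.
#' @param intensity signal vector, same length as `axis`.
#' @param metadata named list of provenance (sample id, seed, noise sigma,
#'   generator parameters...).
#' @return An object of class `"fd_spectrum"`.
#' @export
fd_spectrum <- function(axis, intensity, metadata = list()) {
  stopifnot(is.numeric(axis), is.numeric(intensity))
  if (length(axis) != length(intensity)) {
    stop("axis and intensity must have equal length", call. = FALSE)
  }
  if (length(axis) < 64L) {
    stop("spectrum must have at least 64 points", call. = FALSE)
  }
  d <- diff(axis)
  if (any(!is.finite(axis)) || !(all(d > 0) || all(d < 0))) {
    stop("axis must be strictly monotone and finite", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("intensity contains non-finite values", call. = FALSE)
  }
  descending <- d[1] < 0
  if (descending) {
    axis <- rev(axis)
    intensity <- rev(intensity)
  }
  metadata$axis_was_descending <- isTRUE(metadata$axis_was_descending) ||
    descending
  structure(list(axis = axis, intensity = intensity, metadata = metadata),
            class = "fd_spectrum")
}

#' @export
print.fd_spectrum <- function(x, ...) {
  cat(sprintf("<fd_spectrum> %d points, %.2f to %.2f ppm\n",
              length(x$axis), min(x$axis), max(x$axis)))
  if (!is.null(x$metadata$sample_id)) {
    cat("  sample:", x$metadata$sample_id, "\n")
  }
  invisible(x)
}

#' Area-normalized Lorentzian lineshape
#'
#' The natural NMR absorption profile:
#' `L(d) = (area / pi) * (fwhm/2) / ((d - center)^2 + (fwhm/2)^2)`,
#' whose integral over the whole axis equals `area`. Peak height at the
#' center is `2 * area / (pi * fwhm)`.
#'
#' @param center peak position in ppm.
#' @param fwhm full width at half maximum in ppm, > 0.
#' @param area integrated intensity (arbitrary units).
#' @param axis ppm grid on which to evaluate.
#' @return Intensity vector of `length(axis)`.
#' @export
lorentzian_profile <- function(center, fwhm, area, axis) {
  stopifnot(is.numeric(center), is.numeric(fwhm), is.numeric(area),
            is.numeric(axis))
  if (!is.finite(fwhm) || fwhm <= 0) {
    stop("fwhm must be positive", call. = FALSE)
  }
  g <- fwhm / 2
  (area / pi) * g / ((axis - center)^2 + g^2)
}

#' Expected per-species 19F signal areas
#'
#' Peak areas are proportional to the number of contributing fluorine
#' nuclei. A two-fluorine homodimer contributes one nucleus to each of
#' `A_2F` and `B_2F`; a one-fluorine heterodimer contributes its single
#' nucleus to `A_1F` with probability `p_A`, otherwise to `B_1F`. With
#' dimer fractions `f_homo`/`f_het` over fluorine-visible dimers, the areas
#' per unit total fluorine are
#' `A_2F = B_2F = f_homo / (2 f_homo + f_het)` and
#' `A_1F/B_1F = f_het p_A / (2 f_homo + f_het)` (resp. `p_B`), summing to 1.
#' Equal per-nucleus response is assumed (no relaxation weighting).
#'
#' @param dist a `"species_distribution"` with `p_A`/`p_B` set (see
#'   [set_conformer_populations()]).
#' @return Named numeric vector of areas for `A_2F`, `B_2F`, `A_1F`,
#'   `B_1F`, summing to 1.
#' @examples
#' d <- dimer_species_fractions(mixing_spec(0.25))
#' d <- set_conformer_populations(d, bias_parameters(dg_fw = 0))
#' expected_peak_areas(d) # A_1F/A_2F = 3
#' @export
expected_peak_areas <- function(dist) {
  stopifnot(inherits(dist, "species_distribution"))
  if (!is.finite(dist$p_A) || !is.finite(dist$p_B)) {
    stop("incomplete distribution: conformer populations p_A/p_B unset; ",
         "call set_conformer_populations() first", call. = FALSE)
  }
  total_f <- 2 * dist$f_homo + dist$f_het # fluorines per visible dimer
  c(
    A_2F = dist$f_homo / total_f,
    B_2F = dist$f_homo / total_f,
    A_1F = dist$f_het * dist$p_A / total_f,
    B_1F = dist$f_het * dist$p_B / total_f
  )
}

#' Default simulation grid
#'
#' A 32-ppm window around the tryptophan 19F region. Lorentzian tails are
#' heavy (about `fwhm / (2 pi d)` of the area lies beyond a distance `d`
#' on each side), so the default window is kept wide enough that a
#' noiseless simulated spectrum integrates to its total component area
#' within 0.5%; the acquisition spectral width of the emulated experiment
#' is wider still (50 ppm).
#'
#' The default point spacing (~0.002 ppm, ~77 points per default
#' linewidth) matches the digital resolution of a processed 19F spectrum
#' at 753 MHz (37 kHz sweep, 32-64k points after zero-filling); point
#' density directly controls the variance of fitted peak areas, so an
#' unrealistically coarse grid misstates the attainable precision.
#'
#' @param from,to ppm limits (ascending).
#' @param n number of points.
#' @return Numeric ppm grid.
#' @export
default_ppm_grid <- function(from = -140, to = -108, n = 16384L) {
  seq(from, to, length.out = n)
}

#' Simulate a 1D 19F spectrum of a mixed-labeling sample
#'
#' Composes the full forward model: [dimer_species_fractions()] for the
#' species statistics, [conformer_populations()] of the labeled monomer
#' under the total bias from [labeled_monomer_bias()],
#' [expected_peak_areas()] for the component areas, a sum of Lorentzians at
#' the assignment-table centers, and i.i.d. Gaussian noise. Identical seed
#' and inputs give an identical spectrum.
#'
#' @param spec a [mixing_spec()].
#' @param bias a [bias_parameters()] object.
#' @param table an [assignment_table()]; defaults to the preset matching
#'   `spec$label_kind` for W63-only samples.
#' @param grid ppm axis (ascending); must cover every peak center
#'   +/- 5 fwhm.
#' @param fwhm full width at half maximum in ppm for all peaks (scalar or
#'   named per-species vector). Default 0.15 ppm.
#' @param noise_sigma standard deviation of the additive Gaussian noise, in
#'   the same units as the (unit-total-area) signal. Ignored when `snr`
#'   is given.
#' @param snr alternative noise parameterization: maximum noiseless peak
#'   height divided by `noise_sigma`.
#' @param seed integer seed (mandatory when noise is nonzero).
#' @param sample_id identifier stored in the metadata.
#' @return An [fd_spectrum()] whose metadata records all generator
#'   parameters, the true component areas and the noise draw's seed.
#' @export
simulate_sample_spectrum <- function(spec, bias,
                                     table = NULL,
                                     grid = default_ppm_grid(),
                                     fwhm = 0.15,
                                     noise_sigma = 0,
                                     snr = NULL,
                                     seed = NULL,
                                     sample_id = "synthetic") {
  stopifnot(inherits(spec, "mixing_spec"), inherits(bias, "bias_parameters"))
  if (is.null(table)) {
    table <- assignment_preset(paste0(spec$label_kind, "-W63"))
  }
  stopifnot(inherits(table, "assignment_table"))
  if (length(fwhm) == 1L) fwhm <- setNames(rep(fwhm, 4L), FD_SPECIES)
  stopifnot(setequal(names(fwhm), FD_SPECIES), all(fwhm > 0))
  fwhm <- fwhm[FD_SPECIES]

  dist <- dimer_species_fractions(spec)
  dist <- set_conformer_populations(dist, bias, spec$temperature)
  areas <- expected_peak_areas(dist)

  active <- names(areas)[areas > 0]
  lo <- min(grid); hi <- max(grid)
  for (s in active) {
    ctr <- table$centers[[s]]
    if (ctr - 5 * fwhm[[s]] < lo || ctr + 5 * fwhm[[s]] > hi) {
      stop(sprintf("truncated peak: grid does not cover %s at %.2f ppm %s 5*fwhm",
                   s, ctr, "±"), call. = FALSE)
    }
  }

  signal <- numeric(length(grid))
  for (s in FD_SPECIES) {
    if (areas[[s]] > 0) {
      signal <- signal +
        lorentzian_profile(table$centers[[s]], fwhm[[s]], areas[[s]], grid)
    }
  }

  if (!is.null(snr)) {
    stopifnot(is.numeric(snr), snr > 0)
    noise_sigma <- max(signal) / snr
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  intensity <- signal
  if (noise_sigma > 0) {
    if (is.null(seed)) {
      stop("seed is mandatory when simulating noise", call. = FALSE)
    }
    intensity <- signal +
      with_seed(seed, rnorm(length(grid), 0, noise_sigma))
  }

  fd_spectrum(grid, intensity, metadata = list(
    sample_id = sample_id,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    noise_sigma = noise_sigma,
    fwhm = as.list(fwhm),
    centers = as.list(table$centers),
    true_areas = as.list(areas),
    labeled_ratio = spec$labeled_ratio,
    incorporation_efficiency = spec$incorporation_efficiency,
    label_kind = spec$label_kind,
    temperature = spec$temperature,
    dg_fw = bias$dg_fw,
    dg_mut = bias$dg_mut,
    label_on_mutant = bias$label_on_mutant,
    assumes_statistical_mixing = dist$assumes_statistical_mixing
  ))
}

#' Read / write spectra as tab-separated text
#'
#' The on-disk format is two tab-separated columns (chemical shift in ppm,
#' intensity) preceded by `#`-prefixed header lines; the first header line
#' carries the metadata as JSON (`# METADATA {...}`). A descending ppm axis
#' (the NMR display convention) is accepted on read and normalized to
#' ascending, recording `axis_was_descending` in the metadata. Round-trips
#' are lossless.
#'
#' @param path file path.
#' @return `read_spectrum()` returns an [fd_spectrum()]; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_header <- grepl("^#", lines)
  metadata <- list()
  meta_line <- grep("^# METADATA ", lines, value = TRUE)
  if (length(meta_line) >= 1L) {
    metadata <- jsonlite::fromJSON(sub("^# METADATA ", "", meta_line[1]),
                                   simplifyVector = TRUE)
  }
  body <- lines[!is_header & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 2L)) {
    bad <- which(!is_header & nzchar(trimws(lines)))[which(n_fields != 2L)[1]]
    stop(sprintf("parse error at line %d of %s: expected 2 tab-separated %s",
                 bad, path, "columns"), call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 2L, byrow = TRUE)
  if (any(is.na(mat[, 1]))) {
    bad <- which(is.na(mat[, 1]))[1]
    stop(sprintf("parse error at data row %d of %s: non-numeric ppm value",
                 bad, path), call. = FALSE)
  }
  if (any(is.na(mat[, 2]))) {
    bad <- which(is.na(mat[, 2]))[1]
    stop(sprintf("parse error at data row %d of %s: non-numeric intensity",
                 bad, path), call. = FALSE)
  }
  fd_spectrum(mat[, 1], mat[, 2], metadata = as.list(metadata))
}

#' @param spectrum an [fd_spectrum()].
#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fd_spectrum"))
  meta <- jsonlite::toJSON(spectrum$metadata, auto_unbox = TRUE,
                           digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# METADATA", meta), con)
  writeLines("# ppm\tintensity", con)
  writeLines(sprintf("%.10g\t%.10g", spectrum$axis, spectrum$intensity), con)
  invisible(path)
}

#' Import a fixed-format JCAMP-DX spectrum (read-only convenience)
#'
#' Minimal reader for simple JCAMP-DX files with an `##XYDATA=(X++(Y..Y))`
#' block in plain fixed format (one X value followed by Y values per line,
#' AFFN encoding; no compression schemes). `##FIRSTX`, `##LASTX`,
#' `##NPOINTS`, `##XFACTOR` and `##YFACTOR` are honored.
#'
#' @param path JCAMP-DX file path.
#' @return An [fd_spectrum()].
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    as.numeric(sub(paste0("^##", key, "="), "", hit[1]))
  }
  xfac <- get_field("XFACTOR") %||% 1
  yfac <- get_field("YFACTOR") %||% 1
  start <- grep("^##XYDATA=", lines)
  if (length(start) == 0L) {
    stop("no ##XYDATA block in ", path, call. = FALSE)
  }
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start[1]]
  end <- if (length(stop_at)) stop_at[1] - 1L else length(lines)
  body <- lines[(start[1] + 1L):end]
  body <- body[nzchar(trimws(body))]
  x <- numeric(0); y <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    if (anyNA(vals) || length(vals) < 2L) {
      stop("cannot parse XYDATA line: ", ln, call. = FALSE)
    }
    ys <- vals[-1]
    x <- c(x, rep(vals[1], length(ys))) # placeholder; spacing fixed below
    y <- c(y, ys)
  }
  # Reconstruct the x grid: each line's first number is the X of its first Y,
  # subsequent Ys advance by the uniform spacing from FIRSTX/LASTX/NPOINTS.
  firstx <- get_field("FIRSTX"); lastx <- get_field("LASTX")
  npt <- get_field("NPOINTS") %||% length(y)
  if (!is.null(firstx) && !is.null(lastx) && npt > 1) {
    axis <- seq(firstx * xfac, lastx * xfac, length.out = npt)
  } else {
    axis <- x * xfac
  }
  if (length(axis) != length(y)) {
    stop(sprintf("JCAMP NPOINTS (%d) does not match Y count (%d) in %s",
                 length(axis), length(y), path), call. = FALSE)
  }
  fd_spectrum(axis, y * yfac,
              metadata = list(source = path, format = "jcamp-dx"))
}
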