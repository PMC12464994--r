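# Spectral deconvolution: fit a sum of Lorentzians plus a constant baseline
# by bounded nonlinear least squares, with parameter uncertainties from the
# Jacobian at the optimum, honoring the assignment table's overlap structure
# (unresolved groups are fitted as a single component).

# Parameter layout: for each of m components (center, fwhm, area), then the
# constant baseline: theta = (c1, w1, a1, ..., cm, wm, am, b).

fd_model_eval <- function(theta, axis, m) {
  y <- rep(theta[3 * m + 1], length(axis))
  for (j in seq_len(m)) {
    i <- 3 * (j - 1)
    y <- y + lorentzian_profile(theta[i + 1], theta[i + 2], theta[i + 3],
                                axis)
  }
  y
}

# Analytic Jacobian d(model)/d(theta), n x (3m+1).
fd_model_jacobian <- function(theta, axis, m) {
  n <- length(axis)
  J <- matrix(0, n, 3 * m + 1)
  for (j in seq_len(m)) {
    i <- 3 * (j - 1)
    ctr <- theta[i + 1]; w <- theta[i + 2]; a <- theta[i + 3]
    g <- w / 2
    dx <- axis - ctr
    denom <- dx^2 + g^2
    J[, i + 1] <- (a / pi) * g * 2 * dx / denom^2            # d/d center
    J[, i + 2] <- (a / (2 * pi)) * (dx^2 - g^2) / denom^2    # d/d fwhm
    J[, i + 3] <- (1 / pi) * g / denom                       # d/d area
  }
  J[, 3 * m + 1] <- 1                                        # baseline
  J
}

#' Deconvolve a spectrum into Lorentzian components
#'
#' Fits a sum of Lorentzians plus a constant baseline to the spectrum by
#' bounded nonlinear least squares (`optim(method = "L-BFGS-B")` with
#' analytic gradients). One component is fitted per overlap group of the
#' assignment table: species whose peaks are unresolved share a single
#' Lorentzian whose area is the group total. Component centers are bounded
#' to their assignment windows, widths to `fwhm_bounds`, areas to be
#' nonnegative. Standard errors come from the parameter covariance
#' `s^2 (J'J)^-1` at the optimum, with `s^2` the residual mean square.
#'
#' Deterministic initialization: centers at the window midpoints of the
#' expected shifts, widths at `fwhm_init`, areas from trapezoidal integrals
#' of the baseline-subtracted data over the windows, baseline at the
#' minimum intensity.
#'
#' @param spectrum an [fd_spectrum()].
#' @param table an [assignment_table()].
#' @param fwhm_init initial full width at half maximum in ppm.
#' @param fwhm_bounds length-2 numeric, allowed fwhm range in ppm.
#' @param species character vector of species to include in the model
#'   (default all four). A pure homodimer sample (`f_het = 0`) should be
#'   fitted with `species = c("A_2F", "B_2F")`: free components for
#'   species that cannot be present only absorb noise and bias the real
#'   peaks. [run_sample()] does this automatically from the mixing spec.
#' @param tie_homodimer_areas logical; constrain the `A_2F` and `B_2F`
#'   component areas to be equal. This is the homodimer symmetry the
#'   overlap correction already assumes (`I_A,homo = I_B,homo`), imposed
#'   at the fit stage; it substantially stabilizes the merged B region.
#'   Only available under the `"split"` policy with `B_2F` not merged
#'   away; ignored (with a recorded warning) otherwise. Do not use it when
#'   the point of the fit is to *check* the homodimer symmetry.
#' @param share_fwhm logical; constrain all species components to one
#'   common linewidth (the experimental peaks have equal widths).
#'   Contaminant components keep their own width.
#' @param overlap_policy `"split"` (default) fits one Lorentzian per
#'   species even inside an unresolved overlap group — the individual
#'   areas of near-degenerate components are not separately meaningful,
#'   but their total (the only quantity used downstream) is well
#'   determined and the model class matches the physical signal.
#'   `"merged"` fits each overlap group as a single Lorentzian whose area
#'   is the group total directly.
#' @param extra_peaks optional numeric vector of initial centers for
#'   nuisance (contaminant) components fitted outside the assignment
#'   windows and excluded from species integrals.
#' @param extra_half_window center bound half-width for nuisance components.
#' @param maxit maximum optimizer iterations.
#' @return An object of class `"fd_fit"`: list with `components` (data frame
#'   of group label, members, center, fwhm, area and their standard
#'   errors), `baseline`, `residual_rms`, `reduced_chisq` (against the
#'   metadata noise sigma when known, otherwise `NA`), `converged`,
#'   `warnings` (character; records components pinned at bounds),
#'   `area_covariance` (component-area covariance matrix), and the raw
#'   optimizer output.
#' @export
fit_lorentzians <- function(spectrum, table,
                            fwhm_init = 0.15,
                            fwhm_bounds = c(0.02, 1.0),
                            overlap_policy = c("split", "merged"),
                            species = FD_SPECIES,
                            tie_homodimer_areas = FALSE,
                            share_fwhm = FALSE,
                            extra_peaks = NULL,
                            extra_half_window = 0.2,
                            maxit = 2000L) {
  stopifnot(inherits(spectrum, "fd_spectrum"),
            inherits(table, "assignment_table"))
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(all(species %in% FD_SPECIES), length(species) >= 1L)
  species <- FD_SPECIES[FD_SPECIES %in% species]
  axis <- spectrum$axis
  # Normalize the intensity scale internally so the optimization (and its
  # convergence behaviour) is exactly invariant to rescaling; areas and
  # uncertainties are mapped back at the end.
  y_scale <- max(abs(spectrum$intensity))
  if (y_scale == 0) stop("all-zero spectrum", call. = FALSE)
  y <- spectrum$intensity / y_scale
  dx <- stats::median(diff(axis))
  if (dx * 8 > fwhm_init) {
    stop("spectrum too coarse: need >= 8 points per fwhm", call. = FALSE)
  }

  # One fitted component per entry of `groups`; `labels` names the overlap
  # group each component belongs to (used for group totals downstream),
  # `share` how many components share that group's initialization area.
  overlap_groups <- lapply(table$overlap_groups,
                           function(g) g[g %in% species])
  overlap_groups <- overlap_groups[lengths(overlap_groups) > 0L]
  if (overlap_policy == "merged") {
    groups <- overlap_groups
    labels <- vapply(groups, paste, "", collapse = "+")
    share <- rep(1L, length(groups))
    lo_ctr <- hi_ctr <- ctr0 <- numeric(length(groups))
    for (j in seq_along(groups)) {
      g <- groups[[j]]
      lo_ctr[j] <- min(table$centers[g] - table$half_window[g])
      hi_ctr[j] <- max(table$centers[g] + table$half_window[g])
      ctr0[j] <- mean(table$centers[g])
    }
  } else {
    groups <- as.list(species)
    group_of <- setNames(rep(NA_character_, length(species)), species)
    for (g in overlap_groups) {
      group_of[g] <- paste(g, collapse = "+")
    }
    labels <- unname(group_of[species])
    share <- as.integer(table(labels)[labels])
    lo_ctr <- table$centers[species] - table$half_window[species]
    hi_ctr <- table$centers[species] + table$half_window[species]
    ctr0 <- table$centers[species]
  }
  # Window used for area initialization: the full overlap-group span.
  win_lo <- lo_ctr; win_hi <- hi_ctr
  if (overlap_policy == "split") {
    for (g in overlap_groups) {
      idx <- match(g, species)
      win_lo[idx] <- min(table$centers[g] - table$half_window[g])
      win_hi[idx] <- max(table$centers[g] + table$half_window[g])
    }
  }
  if (!is.null(extra_peaks)) {
    labels <- c(labels, sprintf("contaminant_%d", seq_along(extra_peaks)))
    groups <- c(groups, replicate(length(extra_peaks), character(0),
                                  simplify = FALSE))
    share <- c(share, rep(1L, length(extra_peaks)))
    lo_ctr <- c(lo_ctr, extra_peaks - extra_half_window)
    hi_ctr <- c(hi_ctr, extra_peaks + extra_half_window)
    win_lo <- c(win_lo, extra_peaks - extra_half_window)
    win_hi <- c(win_hi, extra_peaks + extra_half_window)
    ctr0 <- c(ctr0, extra_peaks)
  }
  m <- length(groups)
  if (min(lo_ctr) < min(axis) || max(hi_ctr) > max(axis)) {
    stop("spectrum does not cover all assignment windows", call. = FALSE)
  }

  base0 <- min(y)
  area0 <- numeric(m)
  for (j in seq_len(m)) {
    sel <- axis >= win_lo[j] & axis <= win_hi[j]
    if (sum(sel) >= 2L) {
      tz <- sum(diff(axis[sel]) *
                  (head(y[sel] - base0, -1) + tail(y[sel] - base0, -1)) / 2)
      area0[j] <- max(tz / share[j], 1e-8)
    } else {
      area0[j] <- 1e-8
    }
  }

  theta0 <- numeric(3 * m + 1)
  lower <- numeric(3 * m + 1)
  upper <- numeric(3 * m + 1)
  for (j in seq_len(m)) {
    i <- 3 * (j - 1)
    theta0[i + 1] <- min(max(ctr0[j], lo_ctr[j]), hi_ctr[j])
    theta0[i + 2] <- min(max(fwhm_init, fwhm_bounds[1]), fwhm_bounds[2])
    theta0[i + 3] <- area0[j]
    lower[i + 1] <- lo_ctr[j]; upper[i + 1] <- hi_ctr[j]
    lower[i + 2] <- fwhm_bounds[1]; upper[i + 2] <- fwhm_bounds[2]
    lower[i + 3] <- 0; upper[i + 3] <- Inf
  }
  theta0[3 * m + 1] <- base0
  lower[3 * m + 1] <- -Inf; upper[3 * m + 1] <- Inf
  warnings_out <- character(0)

  # Equality constraints are linear parameter ties: the full parameter
  # vector is theta = phi[map_idx] with phi the free parameters.
  p_full <- 3 * m + 1
  map_idx <- seq_len(p_full)
  is_species <- vapply(groups, function(g) length(g) > 0L, FALSE)
  if (share_fwhm && sum(is_species) > 1L) {
    ref <- which(is_species)[1]
    for (j in which(is_species)[-1]) {
      map_idx[3 * (j - 1) + 2] <- 3 * (ref - 1) + 2
    }
  }
  if (tie_homodimer_areas) {
    ja <- which(vapply(groups, function(g) identical(g, "A_2F"), FALSE))
    jb <- which(vapply(groups, function(g) identical(g, "B_2F"), FALSE))
    if (length(ja) == 1L && length(jb) == 1L) {
      map_idx[3 * (jb - 1) + 3] <- 3 * (ja - 1) + 3
    } else {
      warnings_out <- c(warnings_out,
                        "tie_homodimer_areas ignored: A_2F/B_2F not ",
                        "fitted as separate components")
    }
  }
  free_idx <- sort(unique(map_idx))
  to_free <- match(map_idx, free_idx) # theta = phi[to_free]
  expand <- function(phi) phi[to_free]

  ssr <- function(ph) {
    sum((y - fd_model_eval(expand(ph), axis, m))^2)
  }
  ssr_grad <- function(ph) {
    th <- expand(ph)
    r <- y - fd_model_eval(th, axis, m)
    g_full <- -2 * drop(crossprod(fd_model_jacobian(th, axis, m), r))
    drop(rowsum(g_full, to_free))
  }
  opt <- stats::optim(theta0[free_idx], ssr, ssr_grad,
                      method = "L-BFGS-B",
                      lower = lower[free_idx], upper = upper[free_idx],
                      control = list(maxit = maxit, factr = 1e3))
  theta <- expand(opt$par)
  converged <- opt$convergence == 0L
  if (!converged) {
    warnings_out <- c(warnings_out,
                      sprintf("optimizer did not converge (code %d): %s",
                              opt$convergence, opt$message %||% ""))
  }
  tol <- 1e-8
  for (j in seq_len(m)) {
    i <- 3 * (j - 1)
    if (theta[i + 1] <= lower[i + 1] + tol ||
        theta[i + 1] >= upper[i + 1] - tol) {
      warnings_out <- c(warnings_out,
                        sprintf("component %s: center pinned at bound",
                                labels[j]))
    }
    if (theta[i + 2] <= fwhm_bounds[1] + tol ||
        theta[i + 2] >= fwhm_bounds[2] - tol) {
      warnings_out <- c(warnings_out,
                        sprintf("component %s: fwhm pinned at bound",
                                labels[j]))
    }
  }

  n <- length(axis)
  p <- length(free_idx)
  resid <- y - fd_model_eval(theta, axis, m)
  s2 <- sum(resid^2) / max(n - p, 1L)
  # Jacobian in the free parameterization: columns of tied parameters sum
  J <- fd_model_jacobian(theta, axis, m)
  J_free <- t(rowsum(t(J), to_free))
  JtJ <- crossprod(J_free)
  cov_free <- tryCatch(s2 * solve(JtJ),
                       error = function(e) NULL)
  if (is.null(cov_free)) {
    # Near-zero components (area at the 0 bound) make J'J singular; fall
    # back to the pseudo-inverse so the informative block is still usable.
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-12
    cov_free <- s2 * sv$v[, pos, drop = FALSE] %*%
      diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
    warnings_out <- c(warnings_out,
                      "singular information matrix: pseudo-inverse covariance")
  }
  cov_theta <- cov_free[to_free, to_free, drop = FALSE]
  se <- sqrt(pmax(diag(cov_theta), 0))

  idx_area <- 3 * (seq_len(m) - 1) + 3
  comp <- data.frame(
    group = labels,
    members = vapply(groups, paste, "", collapse = "+"),
    center = theta[3 * (seq_len(m) - 1) + 1],
    fwhm = theta[3 * (seq_len(m) - 1) + 2],
    area = theta[idx_area] * y_scale,
    se_center = se[3 * (seq_len(m) - 1) + 1],
    se_fwhm = se[3 * (seq_len(m) - 1) + 2],
    se_area = se[idx_area] * y_scale,
    stringsAsFactors = FALSE
  )
  area_cov <- cov_theta[idx_area, idx_area, drop = FALSE] * y_scale^2
  dimnames(area_cov) <- list(labels, labels)

  noise_sigma <- spectrum$metadata$noise_sigma
  reduced_chisq <- if (!is.null(noise_sigma) && is.numeric(noise_sigma) &&
                       noise_sigma > 0) {
    sum((resid * y_scale)^2) / noise_sigma^2 / max(n - p, 1L)
  } else NA_real_

  structure(
    list(
      components = comp,
      baseline = theta[p] * y_scale,
      se_baseline = se[p] * y_scale,
      residual_rms = sqrt(mean(resid^2)) * y_scale,
      reduced_chisq = reduced_chisq,
      converged = converged,
      warnings = warnings_out,
      area_covariance = area_cov,
      n_points = n,
      optim = opt
    ),
    class = "fd_fit"
  )
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit> %d components, converged: %s, residual RMS %.3g\n",
              nrow(x$components), x$converged, x$residual_rms))
  print(x$components[, c("group", "center", "fwhm", "area", "se_area")],
        row.names = FALSE, digits = 4)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Map fitted components to named species integrals
#'
#' Resolves the fitted component areas into the integrals entering the
#' equilibrium-constant calculation: `I_A_homo` (the two-fluorine homodimer
#' A signal), `I_A_het` (the one-fluorine heterodimer A signal), and the B
#' intensity. When the B-region peaks are unresolved the merged component
#' total is `I_B` and the heterodimer share is derived through homodimer
#' symmetry (`I_B_homo = I_A_homo`, so `I_B_het = I_B - I_A_homo`); when
#' the table resolves `B_1F` (the E14Q layout) `I_B_het` is read directly.
#'
#' Also reports a mixing consistency score: the relative deviation of
#' `I_A_homo` from the share predicted by the statistical-mixing fractions.
#'
#' @param fit an `"fd_fit"` from [fit_lorentzians()].
#' @param table the [assignment_table()] used for the fit.
#' @param mixing optional `"species_distribution"` (for the consistency
#'   score).
#' @param het_threshold heterodimer A area below this fraction of the total
#'   flags the heterodimer quantities as absent (pure homodimer sample).
#' @return A list of class `"species_integrals"` with `I_A_homo`, `I_A_het`,
#'   `I_B`, `I_B_het` (values with `sigma_` standard errors and
#'   covariances), `b1f_resolved`, `heterodimer_absent`, and
#'   `consistency_score` (or `NA`).
#' @export
assign_species_integrals <- function(fit, table, mixing = NULL,
                                     het_threshold = 1e-3) {
  stopifnot(inherits(fit, "fd_fit"), inherits(table, "assignment_table"))
  if (!fit$converged) {
    stop("fit did not converge; refusing to assign integrals", call. = FALSE)
  }
  comp <- fit$components
  V <- fit$area_covariance
  # Indices of the fitted components carrying the overlap group that
  # contains `species` (one index under the merged policy, possibly
  # several under the split policy).
  group_indices <- function(species, required = TRUE) {
    grp <- NULL
    for (g in table$overlap_groups) if (species %in% g) grp <- g
    if (is.null(grp)) stop("species ", species, " not in table",
                           call. = FALSE)
    hit <- which(vapply(strsplit(comp$members, "+", fixed = TRUE),
                        function(mm) any(mm %in% grp), FALSE))
    if (length(hit) < 1L && required) {
      stop("species ", species, " not mapped to any fitted component",
           call. = FALSE)
    }
    hit
  }
  group_total <- function(idx) {
    list(area = sum(comp$area[idx]),
         sd = sqrt(max(sum(V[idx, idx]), 0)))
  }
  # cov(sum of areas over idx1, sum over idx2)
  group_cov <- function(idx1, idx2) sum(V[idx1, idx2])

  ia_homo_i <- group_indices("A_2F")
  ia_het_i <- group_indices("A_1F", required = FALSE)
  resolved <- b1f_resolved(table)

  a_homo <- group_total(ia_homo_i)
  I_A_homo <- a_homo$area; s_A_homo <- a_homo$sd
  if (length(ia_het_i) == 0L) {
    # heterodimer species excluded from the model (pure homodimer fit)
    ib_i <- group_indices("B_2F")
    b_tot <- group_total(ib_i)
    return(structure(
      list(I_A_homo = I_A_homo, sigma_A_homo = s_A_homo,
           I_A_het = NA_real_, sigma_A_het = NA_real_,
           I_B = b_tot$area, sigma_B = b_tot$sd,
           I_B_het = NA_real_, sigma_B_het = NA_real_,
           cov_Bhet_Ahet = NA_real_,
           cov_B_Ahomo = group_cov(ib_i, ia_homo_i),
           b1f_resolved = resolved, heterodimer_absent = TRUE,
           consistency_score = NA_real_),
      class = "species_integrals"))
  }
  a_het <- group_total(ia_het_i)
  I_A_het <- a_het$area; s_A_het <- a_het$sd

  if (resolved) {
    ib_het_i <- group_indices("B_1F")
    ib_homo_i <- group_indices("B_2F")
    b_het <- group_total(ib_het_i)
    I_B_het <- b_het$area
    s_B_het <- b_het$sd
    I_B <- group_total(ib_homo_i)$area + I_B_het
    s_B <- sqrt(max(sum(V[c(ib_homo_i, ib_het_i), c(ib_homo_i, ib_het_i)]),
                    0))
    cov_Bhet_Ahet <- group_cov(ib_het_i, ia_het_i)
    cov_B_Ahomo <- group_cov(c(ib_homo_i, ib_het_i), ia_homo_i)
  } else {
    ib_i <- group_indices("B_2F") # group holds B_2F and B_1F
    b_tot <- group_total(ib_i)
    I_B <- b_tot$area
    s_B <- b_tot$sd
    I_B_het <- I_B - I_A_homo
    s_B_het <- sqrt(max(s_B^2 + s_A_homo^2 -
                          2 * group_cov(ib_i, ia_homo_i), 0))
    cov_Bhet_Ahet <- group_cov(ib_i, ia_het_i) -
      group_cov(ia_homo_i, ia_het_i)
    cov_B_Ahomo <- group_cov(ib_i, ia_homo_i)
  }

  total <- I_A_homo + I_A_het + I_B
  het_absent <- I_A_het < het_threshold * total
  if (!het_absent && I_B_het < 0) {
    stop("inconsistent integrals: negative heterodimer B intensity ",
         "(misassignment or failed statistical-mixing assumption)",
         call. = FALSE)
  }

  consistency <- NA_real_
  if (!is.null(mixing)) {
    stopifnot(inherits(mixing, "species_distribution"))
    predicted <- mixing$f_homo / (2 * mixing$f_homo + mixing$f_het) * total
    consistency <- abs(I_A_homo - predicted) / predicted
  }

  structure(
    list(
      I_A_homo = I_A_homo, sigma_A_homo = s_A_homo,
      I_A_het = if (het_absent) NA_real_ else I_A_het,
      sigma_A_het = if (het_absent) NA_real_ else s_A_het,
      I_B = I_B, sigma_B = s_B,
      I_B_het = if (het_absent) NA_real_ else I_B_het,
      sigma_B_het = if (het_absent) NA_real_ else s_B_het,
      cov_Bhet_Ahet = if (het_absent) NA_real_ else cov_Bhet_Ahet,
      cov_B_Ahomo = cov_B_Ahomo,
      b1f_resolved = resolved,
      heterodimer_absent = het_absent,
      consistency_score = consistency
    ),
    class = "species_integrals"
  )
}

#' Export the fitted component table as CSV
#'
#' @param fit an `"fd_fit"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  stopifnot(inherits(fit, "fd_fit"))
  utils::write.csv(fit$components, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit result as JSON
#'
#' @param fit an `"fd_fit"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fd_fit"))
  out <- list(
    components = fit$components,
    baseline = fit$baseline,
    residual_rms = fit$residual_rms,
    reduced_chisq = fit$reduced_chisq,
    converged = fit$converged,
    warnings = fit$warnings,
    area_covariance = fit$area_covariance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor",
                       na = "null")
  invisible(path)
}
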