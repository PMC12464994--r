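# Equilibrium constants and free energies from species integrals;
# decomposition of apparent free energies into mutation and fluorine-label
# contributions; replicate combination and error propagation.

#' Construct a free-energy value with uncertainty
#'
#' All free energies in the package carry the pinned sign convention:
#' positive means the distinguished monomer (labeled monomer for label-only
#' samples, mutant monomer for decomposed energies) prefers position A of
#' the dimer.
#'
#' @param value free energy in kcal/mol.
#' @param sigma standard uncertainty in kcal/mol (>= 0, or `NA` if
#'   unknown).
#' @param n_replicates number of independent measurements behind the value.
#' @param sigma_kind how `sigma` was obtained: `"propagated"` (first-order
#'   or Monte-Carlo propagation), `"replicate_sd"` (scatter of independent
#'   replicates) or `"none"`. The two uncertainty kinds are never silently
#'   mixed.
#' @param provenance which operation produced the value.
#' @return An object of class `"free_energy"`.
#' @export
free_energy <- function(value, sigma = NA_real_, n_replicates = 1L,
                        sigma_kind = c("none", "propagated",
                                       "replicate_sd"),
                        provenance = "user") {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  sigma_kind <- match.arg(sigma_kind)
  if (!is.na(sigma)) {
    stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
    if (sigma_kind == "none") sigma_kind <- "propagated"
  }
  structure(
    list(value = value, sigma = as.numeric(sigma),
         n_replicates = as.integer(n_replicates),
         sigma_kind = sigma_kind,
         convention = FD_SIGN_CONVENTION,
         provenance = provenance),
    class = "free_energy"
  )
}

#' @export
print.free_energy <- function(x, ...) {
  s <- if (is.na(x$sigma)) "" else sprintf(" +/- %.2g", x$sigma)
  n <- if (x$n_replicates > 1L) sprintf(" (n = %d)", x$n_replicates) else ""
  cat(sprintf("<free_energy> %.3g%s kcal/mol%s  [%s; %s]\n",
              x$value, s, n, x$sigma_kind, x$convention))
  invisible(x)
}

#' Equilibrium constant from resolved heterodimer integrals
#'
#' The population ratio of the two heterodimer conformations written in the
#' B-over-A orientation, `K = p_B,het / p_A,het = I_B,het / I_A,het`.
#' Note this orientation is opposite to the toward-A constant used by
#' [dg_from_k()] and [conformer_populations()]; invert before converting
#' (see `vignette("conformational-free-energy")`).
#'
#' @param I_A_het integral of the heterodimer A signal (> 0).
#' @param I_B_het integral of the heterodimer B signal (>= 0).
#' @return K (dimensionless). `K = 0` (complete A preference) is returned
#'   but is a boundary: no finite free energy corresponds to it.
#' @export
k_from_integrals <- function(I_A_het, I_B_het) {
  stopifnot(is.numeric(I_A_het), is.numeric(I_B_het))
  if (!is.finite(I_A_het) || I_A_het <= 0) {
    stop("I_A_het must be positive", call. = FALSE)
  }
  if (I_B_het < 0) stop("I_B_het must be >= 0", call. = FALSE)
  I_B_het / I_A_het
}

#' Overlap-corrected equilibrium constant
#'
#' When the heterodimer B signal overlaps the homodimer B signal, only the
#' merged B intensity `I_B = I_B,homo + I_B,het` is measurable. Because the
#' two homodimer signals have equal populations and integrals
#' (`I_A,homo = I_B,homo`), the heterodimer share is recovered by
#' subtraction: `K = (I_B - I_A,homo) / I_A,het` (same B-over-A orientation
#' as [k_from_integrals()]).
#'
#' @param I_B_total merged B-region integral.
#' @param I_A_homo homodimer A integral (equals the hidden `I_B,homo`).
#' @param I_A_het heterodimer A integral (> 0).
#' @return K (dimensionless).
#' @export
k_corrected <- function(I_B_total, I_A_homo, I_A_het) {
  stopifnot(is.numeric(I_B_total), is.numeric(I_A_homo),
            is.numeric(I_A_het))
  if (!is.finite(I_A_het) || I_A_het <= 0) {
    stop("I_A_het must be positive", call. = FALSE)
  }
  if (I_A_homo < 0) stop("I_A_homo must be >= 0", call. = FALSE)
  if (I_B_total < I_A_homo) {
    stop("negative corrected intensity: I_B_total < I_A_homo",
         call. = FALSE)
  }
  (I_B_total - I_A_homo) / I_A_het
}

#' Free energy from a toward-A equilibrium constant
#'
#' `dG = R T ln K` with `K` the toward-A constant `p_A / p_B`, so that a
#' positive free energy means the distinguished monomer prefers position A
#' (the package's pinned convention). This is the exact inverse of
#' [conformer_populations()]. An integral ratio from [k_from_integrals()]
#' or [k_corrected()] is B-over-A oriented and must be inverted first;
#' [dg_app_from_integrals()] does this for you.
#'
#' @param K toward-A equilibrium constant, > 0.
#' @param temperature temperature in kelvin.
#' @return A [free_energy()] (sigma `NA`).
#' @examples
#' dg_from_k(3.664, 310) # ~0.800 kcal/mol
#' @export
dg_from_k <- function(K, temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.numeric(K), length(K) == 1L)
  if (!is.finite(K) || K <= 0) {
    stop("K must be positive and finite", call. = FALSE)
  }
  free_energy(rt_kcal(temperature) * log(K), provenance = "dg_from_k")
}

#' Apparent free energy straight from species integrals
#'
#' Applies the overlap correction when needed and maps the B-over-A
#' integral ratio into the pinned toward-A sign convention:
#' `dG_app = R T ln(I_A,het / (I_B - I_A,homo))` (merged B region) or
#' `R T ln(I_A,het / I_B,het)` (resolved). Positive = labeled monomer
#' prefers A.
#'
#' @param integrals a `"species_integrals"` from
#'   [assign_species_integrals()], or a list with at least `I_A_het` and
#'   either `I_B_het` or both `I_B` and `I_A_homo`.
#' @param temperature temperature in kelvin.
#' @param sigma optional precomputed uncertainty to attach (see
#'   [propagate_integral_errors()]).
#' @return A [free_energy()].
#' @export
dg_app_from_integrals <- function(integrals,
                                  temperature = DEFAULT_TEMPERATURE,
                                  sigma = NA_real_) {
  if (isTRUE(integrals$heterodimer_absent)) {
    stop("heterodimer signals absent: no apparent free energy defined",
         call. = FALSE)
  }
  K <- if (!is.null(integrals$I_B_het) && is.finite(integrals$I_B_het)) {
    k_from_integrals(integrals$I_A_het, integrals$I_B_het)
  } else {
    k_corrected(integrals$I_B, integrals$I_A_homo, integrals$I_A_het)
  }
  if (K <= 0) {
    stop("boundary: zero heterodimer B intensity gives K = 0, ",
         "free energy undefined", call. = FALSE)
  }
  dg <- dg_from_k(1 / K, temperature)
  dg$sigma <- as.numeric(sigma)
  if (!is.na(sigma)) dg$sigma_kind <- "propagated"
  dg$provenance <- "dg_app_from_integrals"
  dg
}

#' Free energy of a pure homodimer sample (null control)
#'
#' For a fully labeled homodimer the two monomer positions are occupied by
#' identical chains, so the conformational free-energy difference is zero
#' by symmetry; this function measures it from the two homodimer integrals
#' as `dG = R T ln(I_A,homo / I_B,homo)` with delta-method uncertainty. Used
#' as the experiment's null check.
#'
#' @param integrals a `"species_integrals"` with the heterodimer flagged
#'   absent (or any list with `I_A_homo`, `I_B` and their sigmas).
#' @param temperature temperature in kelvin.
#' @return A [free_energy()] (provenance `"homodimer_null"`).
#' @export
dg_homodimer_null <- function(integrals,
                              temperature = DEFAULT_TEMPERATURE) {
  rt <- rt_kcal(temperature)
  IA <- integrals$I_A_homo
  IB <- integrals$I_B
  if (IA <= 0 || IB <= 0) {
    stop("homodimer integrals must be positive", call. = FALSE)
  }
  cv <- integrals$cov_B_Ahomo %||% 0
  if (is.na(cv)) cv <- 0
  v <- rt^2 * (integrals$sigma_A_homo^2 / IA^2 +
                 integrals$sigma_B^2 / IB^2 - 2 * cv / (IA * IB))
  fe <- free_energy(rt * log(IA / IB),
                    sigma = sqrt(max(v, 0)),
                    sigma_kind = "propagated",
                    provenance = "homodimer_null")
  fe
}

#' Isolate the mutation free energy from an apparent free energy
#'
#' The measured apparent bias contains both the mutation and the
#' fluorine-label contributions: `dG_app = dG_mut + dG_FW` when label and
#' mutation share a monomer, `dG_app = dG_mut - dG_FW` when they sit on
#' opposite monomers (both referenced to the mutant monomer). Uncertainties
#' combine in quadrature.
#'
#' @param dg_app apparent free energy ([free_energy()] or numeric).
#' @param dg_fw fluorine-label free energy ([free_energy()] or numeric).
#' @param label_on_mutant logical; `TRUE` when the fluorine sits on the
#'   mutant monomer.
#' @return A [free_energy()] for the mutation alone.
#' @examples
#' decompose_mutation_energy(free_energy(2.3, 0.1), free_energy(0.8, 0.2),
#'                           label_on_mutant = TRUE)  # 1.5 +/- 0.22
#' @export
decompose_mutation_energy <- function(dg_app, dg_fw, label_on_mutant) {
  dg_app <- as_free_energy(dg_app)
  dg_fw <- as_free_energy(dg_fw)
  stopifnot(is.logical(label_on_mutant), length(label_on_mutant) == 1L,
            !is.na(label_on_mutant))
  value <- if (label_on_mutant) dg_app$value - dg_fw$value
           else dg_app$value + dg_fw$value
  sigma <- sqrt(sum(c(dg_app$sigma, dg_fw$sigma)^2, na.rm = TRUE))
  if (is.na(dg_app$sigma) && is.na(dg_fw$sigma)) sigma <- NA_real_
  free_energy(value, sigma,
              n_replicates = dg_app$n_replicates,
              sigma_kind = if (is.na(sigma)) "none" else "propagated",
              provenance = "decompose")
}

as_free_energy <- function(x) {
  if (inherits(x, "free_energy")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(free_energy(x))
  stop("expected a free_energy or a single number", call. = FALSE)
}

#' Combine replicate free energies
#'
#' Unweighted mean of the values. The uncertainty follows the reporting
#' rule of the experiment: the scatter (standard deviation) of independent
#' raw replicates when the inputs are single raw measurements, otherwise
#' first-order propagation `sqrt(sum(sigma^2)) / n` of the inputs' own
#' uncertainties (e.g. when averaging two already-decomposed labeling
#' schemes). The two kinds are tagged, never mixed.
#'
#' @param values list of [free_energy()] objects (or a numeric vector).
#' @param method `"auto"` (default: replicate scatter for raw single
#'   measurements, propagation otherwise), `"sd"` or `"propagate"`.
#' @return A [free_energy()] with `n_replicates = length(values)`.
#' @examples
#' combine_replicates(list(free_energy(1.5, 0.2, sigma_kind = "propagated",
#'                                     provenance = "decompose"),
#'                         free_energy(1.56, 0.2, sigma_kind = "propagated",
#'                                     provenance = "decompose")))
#' @export
combine_replicates <- function(values, method = c("auto", "sd",
                                                  "propagate")) {
  method <- match.arg(method)
  if (is.numeric(values)) values <- lapply(values, free_energy)
  stopifnot(is.list(values), length(values) >= 1L)
  values <- lapply(values, as_free_energy)
  conv <- unique(vapply(values, function(v) v$convention, ""))
  stopifnot(length(conv) == 1L)
  v <- vapply(values, function(x) x$value, 0)
  s <- vapply(values, function(x) x$sigma, 0)
  n <- length(v)
  if (method == "auto") {
    raw <- all(vapply(values, function(x) {
      x$n_replicates == 1L && x$provenance %in% c("dg_from_k",
                                                  "dg_app_from_integrals",
                                                  "homodimer_null",
                                                  "raw", "user")
    }, FALSE))
    method <- if (raw && n >= 2L) "sd" else "propagate"
  }
  if (method == "sd") {
    sigma <- if (n >= 2L) stats::sd(v) else NA_real_
    kind <- if (n >= 2L) "replicate_sd" else "none"
  } else {
    if (any(is.na(s))) {
      sigma <- NA_real_
      kind <- "none"
    } else {
      sigma <- sqrt(sum(s^2)) / n
      kind <- "propagated"
    }
  }
  free_energy(mean(v), sigma, n_replicates = n, sigma_kind = kind,
              provenance = "combine_replicates")
}

#' Average the two labeling schemes of a heterodimer pair
#'
#' The experiment measures each mutant heterodimer twice, with the
#' fluorine on the mutant monomer (`dG_app = dG_mut + dG_FW`) and on the
#' unmutated partner (`dG_app = dG_mut - dG_FW`). Averaging the two
#' decomposed mutation energies cancels the label term — including its
#' uncertainty, since the same `dG_FW` enters both schemes with opposite
#' sign and is perfectly correlated between them:
#' `dG_mut = (dG_app,same + dG_app,opp) / 2`,
#' `sigma = sqrt(sigma_same^2 + sigma_opp^2) / 2`.
#' This correlation-aware average is what makes the combined uncertainty
#' smaller than either single-scheme decomposition.
#'
#' @param dg_app_same apparent free energy with the label on the mutant
#'   monomer ([free_energy()] or numeric).
#' @param dg_app_opposite apparent free energy with the label on the
#'   unmutated partner.
#' @return A [free_energy()] for the mutation alone (provenance
#'   `"scheme_average"`).
#' @examples
#' average_labeling_schemes(free_energy(2.3, 0.1), free_energy(0.76, 0.05))
#' @export
average_labeling_schemes <- function(dg_app_same, dg_app_opposite) {
  a <- as_free_energy(dg_app_same)
  b <- as_free_energy(dg_app_opposite)
  sigma <- if (is.na(a$sigma) || is.na(b$sigma)) NA_real_
           else sqrt(a$sigma^2 + b$sigma^2) / 2
  free_energy((a$value + b$value) / 2, sigma,
              n_replicates = a$n_replicates + b$n_replicates,
              sigma_kind = if (is.na(sigma)) "none" else "propagated",
              provenance = "scheme_average")
}

#' Fold change of the conformational equilibrium
#'
#' The factor by which a free-energy difference shifts the two-state
#' equilibrium, `exp(|dG| / (R T))`.
#'
#' @param dg a [free_energy()] or numeric value in kcal/mol.
#' @param temperature temperature in kelvin.
#' @return Dimensionless fold change (>= 1).
#' @examples
#' fold_change(1.5, 310) # ~11.4
#' @export
fold_change <- function(dg, temperature = DEFAULT_TEMPERATURE) {
  dg <- as_free_energy(dg)
  exp(abs(dg$value) / rt_kcal(temperature))
}

#' Propagate integral uncertainties to the free energy
#'
#' First-order (delta-method) or Monte-Carlo propagation of the fitted
#' integral uncertainties through the overlap-corrected equilibrium
#' constant and `dG = R T ln K`. The delta method uses
#' `var(dG) = (RT)^2 (s_A^2/I_A^2 + s_Bhet^2/I_Bhet^2
#'            - 2 cov(I_Bhet, I_A)/(I_A I_Bhet))`.
#' The Monte-Carlo route draws integral pairs from a bivariate normal with
#' the same covariance (seeded) and returns the empirical standard
#' deviation; draws with nonpositive integrals are discarded.
#'
#' @param integrals a `"species_integrals"` from
#'   [assign_species_integrals()].
#' @param temperature temperature in kelvin.
#' @param method `"covariance"` (delta method, default) or `"monte_carlo"`.
#' @param seed integer seed (Monte-Carlo only).
#' @param n_draws number of Monte-Carlo draws.
#' @return Standard uncertainty of the apparent free energy, in kcal/mol.
#' @export
propagate_integral_errors <- function(integrals,
                                      temperature = DEFAULT_TEMPERATURE,
                                      method = c("covariance",
                                                 "monte_carlo"),
                                      seed = 1L, n_draws = 1000L) {
  method <- match.arg(method)
  stopifnot(inherits(integrals, "species_integrals"))
  if (isTRUE(integrals$heterodimer_absent)) {
    stop("heterodimer signals absent: nothing to propagate", call. = FALSE)
  }
  rt <- rt_kcal(temperature)
  IA <- integrals$I_A_het
  IBh <- integrals$I_B_het
  sA <- integrals$sigma_A_het
  sBh <- integrals$sigma_B_het
  cv <- integrals$cov_Bhet_Ahet %||% 0
  if (is.na(cv)) cv <- 0
  if (sA == 0 && sBh == 0) return(0)
  if (IBh <= 0) stop("boundary integrals (I_B_het <= 0): uncertainty ",
                     "undefined", call. = FALSE)
  if (method == "covariance") {
    v <- rt^2 * (sA^2 / IA^2 + sBh^2 / IBh^2 - 2 * cv / (IA * IBh))
    if (v < 0) {
      warning("negative delta-method variance (degenerate covariance); ",
              "falling back to Monte-Carlo")
      return(propagate_integral_errors(integrals, temperature,
                                       "monte_carlo", seed, n_draws))
    }
    return(sqrt(v))
  }
  # Monte-Carlo: bivariate normal draws of (I_A_het, I_B_het).
  S <- matrix(c(sA^2, cv, cv, sBh^2), 2, 2)
  L <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(L)) {
    # covariance not positive definite: drop the cross-term
    L <- chol(matrix(c(sA^2, 0, 0, sBh^2), 2, 2))
  }
  draws <- with_seed(seed, {
    z <- matrix(rnorm(2L * n_draws), ncol = 2L)
    sweep(z %*% L, 2L, c(IA, IBh), "+")
  })
  ok <- draws[, 1] > 0 & draws[, 2] > 0
  if (mean(ok) < 0.5) {
    warning("more than half of the Monte-Carlo draws hit nonpositive ",
            "integrals; uncertainty is unreliable at this SNR")
  }
  dg <- rt * log(draws[ok, 1] / draws[ok, 2])
  stats::sd(dg)
}
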