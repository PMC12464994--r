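# Statistical mixing of labeled and unlabeled monomers into dimers, and the
# two-state Boltzmann populations of the one-fluorine heterodimer.

#' Describe the composition of one mixed-labeling NMR sample
#'
#' A sample is prepared by mixing a 19F-labeled protein with an unlabeled
#' partner at a molar ratio; monomers pair into dimers. `labeled_ratio` is
#' the mole fraction of the labeled protein among total protein (a 1:3
#' labeled:unlabeled sample has `labeled_ratio = 0.25`);
#' `incorporation_efficiency` is the fraction of the nominally labeled pool
#' that actually carries fluorine (fluoro-tryptophan incorporation is not
#' always complete).
#'
#' @param labeled_ratio mole fraction in (0, 1] of the labeled protein.
#' @param incorporation_efficiency fraction in (0, 1] of the labeled pool
#'   carrying 19F. Default 1.
#' @param labeled_variant identifier of the labeled protein (e.g. `"W63"`,
#'   `"W63+L51I"`).
#' @param unlabeled_variant identifier of the unlabeled partner.
#' @param label_kind `"5FW"` or `"6FW"` (fluorine at the 5' or 6' indole
#'   position of tryptophan).
#' @param temperature sample temperature in kelvin. Default 310 K.
#' @return An object of class `"mixing_spec"`.
#' @examples
#' mixing_spec(0.25) # the paper's canonical 1:3 sample
#' @export
mixing_spec <- function(labeled_ratio,
                        incorporation_efficiency = 1.0,
                        labeled_variant = "W63",
                        unlabeled_variant = "W63",
                        label_kind = c("5FW", "6FW"),
                        temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.numeric(labeled_ratio), length(labeled_ratio) == 1L,
            is.numeric(incorporation_efficiency),
            length(incorporation_efficiency) == 1L)
  label_kind <- match.arg(label_kind)
  if (!is.finite(labeled_ratio) || labeled_ratio <= 0 || labeled_ratio > 1) {
    stop("labeled_ratio must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(incorporation_efficiency) ||
      incorporation_efficiency <= 0 || incorporation_efficiency > 1) {
    stop("incorporation_efficiency must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  structure(
    list(
      labeled_ratio = labeled_ratio,
      incorporation_efficiency = incorporation_efficiency,
      labeled_variant = as.character(labeled_variant),
      unlabeled_variant = as.character(unlabeled_variant),
      label_kind = label_kind,
      temperature = temperature
    ),
    class = "mixing_spec"
  )
}

#' @export
print.mixing_spec <- function(x, ...) {
  cat(sprintf(
    "<mixing_spec> %s-%s : %s  ratio %.4g, incorporation %.4g, T = %g K\n",
    x$label_kind, x$labeled_variant, x$unlabeled_variant,
    x$labeled_ratio, x$incorporation_efficiency, x$temperature))
  invisible(x)
}

#' Mutation and fluorine-label conformational biases of a heterodimer
#'
#' Free-energy biases, in kcal/mol, pushing the distinguished monomer toward
#' position A: `dg_fw` is the bias induced by the fluoro-tryptophan label
#' itself, `dg_mut` the bias of the mutation. `label_on_mutant` records
#' whether the fluorine and the mutation sit on the same monomer (the two
#' labeling schemes of the experiment).
#'
#' @param dg_fw fluorine-label bias in kcal/mol (positive = labeled monomer
#'   prefers A).
#' @param dg_mut mutation bias in kcal/mol (positive = mutant monomer
#'   prefers A). Default 0 (label-only sample).
#' @param label_on_mutant logical; `TRUE` when fluorine and mutation reside
#'   on the same monomer.
#' @return An object of class `"bias_parameters"`.
#' @export
bias_parameters <- function(dg_fw, dg_mut = 0, label_on_mutant = TRUE) {
  stopifnot(is.numeric(dg_fw), length(dg_fw) == 1L,
            is.numeric(dg_mut), length(dg_mut) == 1L,
            is.logical(label_on_mutant), length(label_on_mutant) == 1L,
            !is.na(label_on_mutant))
  if (!is.finite(dg_fw) || !is.finite(dg_mut)) {
    stop("bias free energies must be finite", call. = FALSE)
  }
  structure(
    list(dg_fw = dg_fw, dg_mut = dg_mut,
         label_on_mutant = label_on_mutant),
    class = "bias_parameters"
  )
}

#' Dimer species fractions under statistical mixing
#'
#' Assuming binomial (statistical) pairing with no preferential association,
#' a monomer carries fluorine with probability
#' `q = labeled_ratio * incorporation_efficiency`, so dimers split into
#' two-fluorine (`f_2F = q^2`), one-fluorine (`f_1F = 2 q (1 - q)`) and
#' unlabeled (`f_0F = (1 - q)^2`) species. Among the fluorine-visible dimers
#' the homodimer and heterodimer fractions are
#' `f_homo = f_2F / (f_2F + f_1F)` and `f_het = 1 - f_homo`; at a 1:3 ratio
#' with full incorporation these are 1/7 and 6/7.
#'
#' @param spec a [mixing_spec()].
#' @return An object of class `"species_distribution"`: list with `f_2F`,
#'   `f_1F`, `f_0F` (fractions over all dimers), `f_homo`, `f_het`
#'   (fractions over fluorine-visible dimers), `p_A`/`p_B` (unset, `NA`;
#'   see [conformer_populations()]), and `assumes_statistical_mixing = TRUE`.
#' @examples
#' dimer_species_fractions(mixing_spec(0.25))$f_homo # 1/7
#' @export
dimer_species_fractions <- function(spec) {
  stopifnot(inherits(spec, "mixing_spec"))
  q <- spec$labeled_ratio * spec$incorporation_efficiency
  if (q <= 0) stop("no fluorine-visible species (q = 0)", call. = FALSE)
  f_2F <- q^2
  f_1F <- 2 * q * (1 - q)
  f_0F <- (1 - q)^2
  f_homo <- f_2F / (f_2F + f_1F)
  structure(
    list(
      f_2F = f_2F, f_1F = f_1F, f_0F = f_0F,
      f_homo = f_homo, f_het = 1 - f_homo,
      p_A = NA_real_, p_B = NA_real_,
      assumes_statistical_mixing = TRUE
    ),
    class = "species_distribution"
  )
}

#' Two-state conformer populations from a free-energy bias
#'
#' In a one-fluorine heterodimer the distinguished monomer occupies position
#' A or B; the populations follow the Boltzmann two-state partition function
#' with toward-A equilibrium constant `K' = exp(dG / (R T))`:
#' `p_A = K' / (1 + K')`, `p_B = 1 / (1 + K')`.
#'
#' @param dg_total total conformational bias in kcal/mol; positive means the
#'   distinguished monomer prefers position A.
#' @param temperature temperature in kelvin.
#' @return Named numeric vector `c(p_A = , p_B = )`, summing to 1.
#' @examples
#' conformer_populations(0.8, 310) # p_A ~ 0.786
#' @export
conformer_populations <- function(dg_total,
                                  temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.numeric(dg_total), length(dg_total) == 1L)
  if (!is.finite(dg_total)) stop("dg_total must be finite", call. = FALSE)
  rt <- rt_kcal(temperature)
  k <- exp(dg_total / rt)
  c(p_A = k / (1 + k), p_B = 1 / (1 + k))
}

#' Attach heterodimer conformer populations to a species distribution
#'
#' @param dist a `"species_distribution"` from [dimer_species_fractions()].
#' @param bias a [bias_parameters()] object.
#' @param temperature temperature in kelvin.
#' @return The distribution with `p_A`/`p_B` filled in for the labeled
#'   monomer of the heterodimer.
#' @export
set_conformer_populations <- function(dist, bias,
                                      temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(dist, "species_distribution"),
            inherits(bias, "bias_parameters"))
  p <- conformer_populations(labeled_monomer_bias(bias), temperature)
  dist$p_A <- unname(p["p_A"])
  dist$p_B <- unname(p["p_B"])
  dist
}

#' Total apparent bias of the mutant monomer toward position A
#'
#' The apparent free energy measured on a heterodimer sample contains both
#' the mutation bias and the fluorine-label bias. When label and mutation
#' share a monomer the contributions add; when they sit on opposite
#' monomers the label bias, referenced to the mutant monomer, flips sign:
#' `dG_app = dG_mut + dG_FW` (same monomer) or `dG_mut - dG_FW` (opposite).
#'
#' @param params a [bias_parameters()] object.
#' @return Apparent bias in kcal/mol, referenced to the mutant monomer.
#' @examples
#' heterodimer_bias(bias_parameters(0.8, 1.5, TRUE))  # 2.3
#' heterodimer_bias(bias_parameters(0.8, 1.6, FALSE)) # 0.8
#' @export
heterodimer_bias <- function(params) {
  stopifnot(inherits(params, "bias_parameters"))
  if (params$label_on_mutant) params$dg_mut + params$dg_fw
  else params$dg_mut - params$dg_fw
}

#' Total bias of the labeled monomer toward position A
#'
#' The spectrum reports where the *labeled* monomer sits. Referenced to the
#' labeled monomer the mutation term flips sign when the mutation is on the
#' opposite monomer: `dG = dG_FW + dG_mut` (label on mutant) or
#' `dG = dG_FW - dG_mut` (label on the other monomer).
#'
#' @param params a [bias_parameters()] object.
#' @return Bias in kcal/mol, referenced to the labeled monomer.
#' @export
labeled_monomer_bias <- function(params) {
  stopifnot(inherits(params, "bias_parameters"))
  if (params$label_on_mutant) params$dg_fw + params$dg_mut
  else params$dg_fw - params$dg_mut
}
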