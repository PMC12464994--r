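---
title: "Quantifying conformational free energies of an asymmetric dimer from 1D 19F NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational free energies of an asymmetric dimer from 1D 19F NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluordimer)
```

## The model

EmrE is an antiparallel, asymmetric homodimer: its two identical monomers
occupy structurally distinct positions A and B, and alternating access
exchanges the two assignments. For the unperturbed homodimer the two
orientations are the same state relabeled, so their populations are equal
and the conformational free-energy difference is exactly zero. Any
perturbation confined to one monomer — a point mutation, or the single
hydrogen-to-fluorine substitution introduced by a fluoro-tryptophan
label — breaks the degeneracy. In a heterodimer where only one monomer is
distinguishable, the population ratio of the two orientations is a
two-state Boltzmann equilibrium,

$$p_A = \frac{K'}{1+K'}, \qquad K' = e^{\Delta G / RT},$$

with $R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $T = 310$ K by
default (the acquisition temperature, 37 °C).

### Sign convention

Throughout the package **positive $\Delta G$ means the distinguished
monomer prefers position A**. This is pinned deliberately. The literature
formula for these experiments writes the equilibrium constant in the
B-over-A orientation, $K = I_{B,het}/I_{A,het}$, together with
$\Delta G = RT\ln K$; taken literally that pair assigns a *negative* free
energy to an A-preferring label, opposite to the signs reported alongside
it. We keep `k_from_integrals()` / `k_corrected()` in the B-over-A
orientation so the familiar intensity arithmetic reads as published, and
define `dg_from_k()` as the exact inverse of the population map (its
argument is the toward-A constant $K' = p_A/p_B$).
`dg_app_from_integrals()` composes the two correctly,
$\Delta G_{app} = RT\ln\!\big(I_{A,het}/(I_B - I_{A,homo})\big)$, and is
what the pipeline uses. With this convention every sign produced by the
package matches the published data: $\Delta G_{5FW} = +0.8$ kcal/mol (the
5-fluoro label prefers A), $\Delta G_{6FW} = -0.2$, and negative apparent
values for the E14Q heterodimers.

### Mixing statistics

Mixing labeled and unlabeled protein at mole fraction $r$ with fluorine
incorporation efficiency $e$ makes any given monomer fluorinated with
probability $q = re$. Assuming statistical (binomial) pairing with no
preferential association — an assumption the experiment makes implicitly
and the package records as a flag in its outputs —

$$f_{2F} = q^2,\quad f_{1F} = 2q(1-q),\quad f_{0F} = (1-q)^2,$$

and among NMR-visible dimers $f_{homo} = f_{2F}/(f_{2F}+f_{1F})$. The
canonical 1:3 sample gives $f_{homo} = 1/7$, $f_{het} = 6/7$.
`incorporation_efficiency` defaults to 1: incomplete incorporation is
reported qualitatively for these samples but never quantified, so the
default describes the idealized sample and the parameter is exposed for
sensitivity analysis.

### Signal model

Peak areas are proportional to the number of contributing ¹⁹F nuclei with
equal per-nucleus response (intensities are integrated without relaxation
correction, as in the source analysis). A 2F homodimer contributes one
nucleus each to the $A_{2F}$ and $B_{2F}$ signals; a 1F heterodimer
contributes its single nucleus to $A_{1F}$ with probability $p_A$, else to
$B_{1F}$. Normalized per unit total fluorine:

$$A_{2F} = B_{2F} = \frac{f_{homo}}{2f_{homo}+f_{het}},\qquad
  A_{1F} = \frac{f_{het}\,p_A}{2f_{homo}+f_{het}}.$$

Two consequences are used as internal checks: the homodimer peaks are
always equal (the conformational bias is invisible in a symmetric
homodimer), and swapping the label onto the other protein mirrors
$A_{1F} \leftrightarrow B_{1F}$.

### The overlap correction

In the 5FW spectra the heterodimer B signal (−123.3 ppm) is not resolved
from the homodimer B signal (−123.2 ppm); only the merged intensity $I_B$
is measurable. Because $I_{A,homo} = I_{B,homo}$ by symmetry, the
heterodimer share is recovered by subtraction:

$$K = \frac{I_B - I_{A,homo}}{I_{A,het}}.$$

When the B heterodimer signal *is* resolved (the E14Q context shifts it to
−122 ppm) the direct ratio is used; on consistent data the two routes are
algebraically identical, which the test suite asserts.

## Tunable parameters

| parameter | units | default | rationale |
|---|---|---|---|
| `labeled_ratio` | mole fraction | 0.25 | the experiment's 1:3 mixing |
| `incorporation_efficiency` | fraction | 1.0 | idealized labeling; no published number |
| `temperature` | K | 310 | acquisition temperature |
| `fwhm` | ppm | 0.15 | linewidths are described as equal but no value is printed; 0.15 ppm is a realistic solution linewidth for a bicelle-reconstituted membrane protein at 753 MHz |
| grid | ppm | 32 ppm / 16384 pts | ~0.002 ppm per point, the digital resolution of a processed spectrum at this field (50 ppm sweep, 32–64k points); see below |
| `snr` | — | user-set | max noiseless peak height over noise sigma |
| `fwhm_bounds` | ppm | [0.02, 1.0] | generous physical range for the fit |

Grid density matters more than it may appear: the variance of a fitted
peak area scales with the point spacing, so simulating on an
unrealistically coarse grid overstates the uncertainty of every downstream
free energy. The default spacing was chosen once from the acquisition
parameters of the emulated experiment, not tuned to any test outcome.

## What the generator emulates — and what it does not

`simulate_sample_spectrum()` produces: 2–4 area-parameterized Lorentzians
at the assignment-table shifts, areas from the mixing × Boltzmann model,
i.i.d. Gaussian noise, deterministic under a seed. The published chemical
shifts are used for the 5FW presets; the 6FW preset's shifts are invented
stand-ins (the experimental values are not printed) and are flagged as
such in `assignment_preset()`.

Not emulated: phase and baseline distortion, apodization artifacts,
field/shim drift, relaxation-weighted intensities, chemical-exchange
broadening, and the fluorine contaminant peaks visible in real bicelle
samples (a nuisance Lorentzian can be injected manually and absorbed by
`extra_peaks`). A green recovery test therefore establishes that the
*analysis* is unbiased and correctly calibrated for spectra obeying the
stated lineshape model — it does not validate robustness to vendor
processing artifacts.

## Numerical choices in the deconvolution

* **Optimizer.** Bounded nonlinear least squares via `optim(L-BFGS-B)`
  with analytic gradients of the Lorentzian model; parameter covariance
  from $s^2 (J^\top J)^{-1}$ with the analytic Jacobian at the optimum.
  The intensity scale is normalized internally, making fits exactly
  scale-equivariant.
* **Initialization** is deterministic: centers at the expected shifts,
  widths at 0.15 ppm, areas from trapezoidal window integrals, baseline at
  the minimum intensity. Reproducibility is preferred over multistart.
* **Overlap policy.** Unresolved groups are fitted as one component per
  *species* (`overlap_policy = "split"`), and only the group **total** is
  propagated downstream, which is all the overlap-corrected constant
  needs. The alternative of one merged Lorentzian per group
  (`"merged"`) is retained as an option but is a lineshape-model mismatch
  whenever the group's true peaks do not coincide (two peaks 0.1 ppm apart
  are not a single Lorentzian), and it biases the recovered free energy by
  about −0.09 kcal/mol in the canonical scenario — which is why it is not
  the default.
* **Degenerate components.** Individual areas within an unresolved group
  are not separately identifiable; their strong negative correlation is
  carried in the covariance so the group-total uncertainty is correct.
  Components pinned at bounds and singular information matrices are
  recorded as warnings (pseudo-inverse fallback), never silently ignored.
* **Impossible species are excluded.** For a pure homodimer sample
  ($f_{het}=0$) the pipeline drops the heterodimer components
  (`species = c("A_2F", "B_2F")`): free components with nothing to fit
  absorb noise from neighboring peaks and would bias the homodimer null.
* **Optional physical constraints.** `share_fwhm` (all peaks one
  linewidth — the experimental observation) and `tie_homodimer_areas`
  ($I_{A,homo} = I_{B,homo}$ imposed at the fit stage) are available but
  default to off; the shipped tests and acceptance runs use the
  unconstrained fit. Do not tie the homodimer areas when the point of the
  measurement is to *check* homodimer symmetry.
* **Baseline** is a single constant offset; the modeled spectra have flat
  baselines and higher-order baseline correction is out of scope.

## Uncertainties

Fitted-area uncertainties propagate to $\Delta G$ either by the delta
method,

$$\sigma^2_{\Delta G} = (RT)^2\left(\frac{\sigma_{A}^2}{I_{A,het}^2} +
\frac{\sigma_{B,het}^2}{I_{B,het}^2} -
\frac{2\,\mathrm{cov}}{I_{A,het} I_{B,het}}\right),$$

or by seeded Monte-Carlo from the integral covariance (1000 draws by
default); the two agree within 20% on well-conditioned fits and the test
suite checks the covariance route against the empirical scatter of 200
noise realizations. Replicate scatter (`sigma_kind = "replicate_sd"`) and
propagated uncertainty (`"propagated"`) are distinct, tagged, and never
silently mixed, mirroring how the published table distinguishes the two.

Averaging the two labeling schemes of a mutant heterodimer deserves care:
the label term enters the two schemes with opposite sign, so in the
average it cancels *exactly, together with its uncertainty*.
`average_labeling_schemes()` implements this correlation-aware average —
$\sigma = \sqrt{\sigma_{same}^2 + \sigma_{opp}^2}/2$ — which is how a
combined value of 1.5 ± 0.1 kcal/mol arises from schemes whose individual
decompositions carry ±0.2. The generic `combine_replicates()` assumes
independent inputs and would overstate that uncertainty.

## Degenerate inputs and tie-breaks

* $I_{B,het} = 0$ is a boundary (complete A preference): $K = 0$ is
  returned by the constant helpers but no finite free energy exists;
  conversion raises an error rather than emitting `-Inf`.
* $I_B < I_{A,homo}$ signals misassignment or failure of the statistical
  mixing assumption and is a hard error.
* A heterodimer A signal below $10^{-3}$ of the total area flags the
  sample as homodimer-only; the pipeline then reports the homodimer null
  free energy $RT\ln(I_{A,homo}/I_{B,homo})$ instead.
* Monte-Carlo propagation discards draws with nonpositive integrals and
  warns when more than half are lost (the uncertainty is then unreliable
  at that SNR).

## Known limitations

* Published free energies for the E14Q rows are reproduced from printed
  apparent free energies (values-only mode); the underlying raw integrals
  are not available in the source material.
* The additivity $\Delta G_{app} = \Delta G_{mut} + \Delta G_{FW}$ is an
  assumption; for labels adjacent to the mutated site (the 5FW/E14Q
  proximity case) an extra coupling term is plausible and is *not*
  modeled — the package reports both labeling schemes so the discrepancy
  is visible rather than hidden.
* Monomer-exchange kinetics between dimers, substrate-bound states, pH
  titration, and temperature dependence are out of scope.
* The recovery experiment's fold-change helper uses $|\Delta G|$; a
  published "~13-fold" figure corresponds to 1.6 kcal/mol
  ($e^{1.6/RT} = 13.4$) rather than 1.5 ($e^{1.5/RT} = 11.4$); the
  package reports the computed value for whichever input it is given.
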