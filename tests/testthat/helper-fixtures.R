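# Shared fixtures: small grids and canonical samples, all generated in code.

RT310 <- 1.9872e-3 * 310

# coarser grid than the default to keep noisy-fit loops fast (~8.4 points
# per default fwhm, just above the fitter's floor)
quick_grid <- function() default_ppm_grid(n = 1792L)

canonical_sample <- function(dg_fw = 0.8, dg_mut = 0,
                             label_on_mutant = TRUE,
                             ratio = 0.25, snr = NULL, seed = NULL,
                             grid = quick_grid(),
                             preset = "5FW-W63") {
  simulate_sample_spectrum(
    mixing_spec(ratio),
    bias_parameters(dg_fw, dg_mut, label_on_mutant),
    table = assignment_preset(preset),
    grid = grid, snr = snr, seed = seed
  )
}

# trapezoidal quadrature
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Independent oracle for the mixing statistics: enumerate the four ordered
# monomer pairs (each monomer labeled with probability q) and read the
# species fractions off the joint probabilities.
enumerate_pair_fractions <- function(q) {
  # ordered pairs: LL, LU, UL, UU
  p <- c(q * q, q * (1 - q), (1 - q) * q, (1 - q) * (1 - q))
  f_2F <- p[1]; f_1F <- p[2] + p[3]; f_0F <- p[4]
  list(f_2F = f_2F, f_1F = f_1F, f_0F = f_0F,
       f_homo = f_2F / (f_2F + f_1F),
       f_het = f_1F / (f_2F + f_1F))
}

# Independent oracle for per-species fluorine signal: enumerate dimers and
# count fluorine nuclei landing in each signal, with the distinguished
# monomer of a 1F dimer sitting in position A with probability p_A.
enumerate_fluorine_areas <- function(q, p_A) {
  fr <- enumerate_pair_fractions(q)
  a <- c(A_2F = fr$f_2F * 1, B_2F = fr$f_2F * 1,
         A_1F = fr$f_1F * p_A, B_1F = fr$f_1F * (1 - p_A))
  a / sum(a)
}

minimal_fit <- function(areas, labels, members, V = NULL) {
  # hand-built fd_fit carrying only what assign_species_integrals() needs
  if (is.null(V)) V <- diag(0, length(areas))
  dimnames(V) <- list(labels, labels)
  structure(list(
    components = data.frame(group = labels, members = members,
                            center = 0, fwhm = 0.15, area = areas,
                            se_center = 0, se_fwhm = 0,
                            se_area = sqrt(diag(V)),
                            stringsAsFactors = FALSE),
    baseline = 0, se_baseline = 0, residual_rms = 0,
    reduced_chisq = NA_real_, converged = TRUE, warnings = character(0),
    area_covariance = V, n_points = 0L, optim = NULL
  ), class = "fd_fit")
}
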