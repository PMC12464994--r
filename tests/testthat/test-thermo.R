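# equilibrium constants, free energies, decomposition, replicates, errors

test_that("equilibrium constants from integrals", {
  expect_identical(k_from_integrals(0.5, 0.5), 1)
  expect_equal(k_from_integrals(0.286, 0.571), 2.0, tolerance = 0.002)
  expect_identical(k_from_integrals(0.3, 0), 0) # boundary: full A preference
  expect_error(k_from_integrals(0, 0.5), "I_A_het")
  expect_error(k_from_integrals(-1, 0.5), "I_A_het")
})

test_that("overlap-corrected constant implements I_B - I_A,homo", {
  expect_equal(k_corrected(0.7143, 0.1429, 0.2857), 2.0, tolerance = 1e-3)
  expect_identical(k_corrected(0.2, 0.2, 0.5), 0)
  expect_error(k_corrected(0.1, 0.2, 0.5), "negative corrected intensity")
  expect_error(k_corrected(0.5, 0.2, 0), "I_A_het")
  # algebraic identity when B_1F is resolved: I_B = I_B,homo + I_B,het
  I_A_homo <- 0.143; I_B_het <- 0.571; I_A_het <- 0.286
  expect_equal(k_corrected(I_A_homo + I_B_het, I_A_homo, I_A_het),
               k_from_integrals(I_A_het, I_B_het), tolerance = 1e-12)
})

test_that("dG = RT ln K with the toward-A convention", {
  expect_identical(dg_from_k(1)$value, 0)
  expect_equal(dg_from_k(3.664, 310)$value, 0.800, tolerance = 1e-3)
  expect_equal(dg_from_k(2, 310)$value, -dg_from_k(1 / 2, 310)$value,
               tolerance = 1e-14)
  expect_error(dg_from_k(0), "positive")
  expect_error(dg_from_k(-2), "positive")
  expect_match(dg_from_k(2)$convention, "prefers A")
})

test_that("dG <-> K round-trips to 1e-12 across the physical range", {
  for (dg in seq(-5, 5, by = 0.25)) {
    K <- exp(dg / RT310)
    expect_equal(dg_from_k(K, 310)$value, dg, tolerance = 1e-12)
    # and the population map inverts consistently
    p <- conformer_populations(dg, 310)
    expect_equal(dg_from_k(p[["p_A"]] / p[["p_B"]], 310)$value, dg,
                 tolerance = 1e-9)
  }
})

test_that("apparent dG from integrals lands on the reported sign", {
  # A-preferring sample: I_A,het > I_B,het must give a positive dG
  ints <- structure(list(I_A_het = 0.589, I_B_het = 0.161,
                         heterodimer_absent = FALSE),
                    class = "species_integrals")
  dg <- dg_app_from_integrals(ints, 310)
  expect_gt(dg$value, 0)
  expect_equal(dg$value, RT310 * log(0.589 / 0.161), tolerance = 1e-12)
})

test_that("mutation decomposition reproduces the published arithmetic", {
  # label and mutation on the same monomer
  m1 <- decompose_mutation_energy(free_energy(2.3, 0.1),
                                  free_energy(0.8, 0.2), TRUE)
  expect_equal(m1$value, 1.5, tolerance = 1e-12)
  expect_equal(m1$sigma, sqrt(0.1^2 + 0.2^2), tolerance = 1e-12)
  # opposite monomers
  m2 <- decompose_mutation_energy(free_energy(0.76, 0.05),
                                  free_energy(0.8, 0.2), FALSE)
  expect_equal(m2$value, 1.56, tolerance = 1e-12)
  expect_equal(signif(m2$value, 2), 1.6)
  # E14Q, label on the unmutated partner
  m3 <- decompose_mutation_energy(free_energy(-1.5),
                                  free_energy(0.8, 0.2), FALSE)
  expect_equal(m3$value, -0.7, tolerance = 1e-12)
  # no label bias: identity
  expect_identical(
    decompose_mutation_energy(free_energy(1.23), free_energy(0), TRUE)$value,
    1.23)
})

test_that("averaging the two labeling schemes cancels the label bias", {
  set.seed(17)
  for (i in 1:20) {
    fw <- runif(1, -1, 1); mut <- runif(1, -2, 2)
    app_same <- heterodimer_bias(bias_parameters(fw, mut, TRUE))
    app_opp <- heterodimer_bias(bias_parameters(fw, mut, FALSE))
    avg <- combine_replicates(list(
      decompose_mutation_energy(free_energy(app_same), free_energy(fw),
                                TRUE),
      decompose_mutation_energy(free_energy(app_opp), free_energy(fw),
                                FALSE)), method = "propagate")
    expect_identical(avg$value, mut)
  }
})

test_that("replicate combination follows the reporting rules", {
  # averaging the two decomposed labeling schemes: propagated sigma
  schemes <- list(
    free_energy(1.5, 0.2, sigma_kind = "propagated",
                provenance = "decompose"),
    free_energy(1.56, 0.2, sigma_kind = "propagated",
                provenance = "decompose"))
  comb <- combine_replicates(schemes)
  expect_equal(comb$value, 1.53, tolerance = 1e-12)
  expect_equal(comb$sigma, sqrt(2 * 0.2^2) / 2, tolerance = 1e-12) # 0.14
  expect_identical(comb$sigma_kind, "propagated")
  expect_equal(signif(comb$value, 2), 1.5)
  expect_equal(round(comb$sigma, 1), 0.1)

  # raw replicates: scatter, tagged replicate_sd
  raw <- lapply(c(0.75, 0.85, 0.8), function(v)
    free_energy(v, 0.05, provenance = "dg_app_from_integrals"))
  comb_raw <- combine_replicates(raw)
  expect_identical(comb_raw$sigma_kind, "replicate_sd")
  expect_equal(comb_raw$value, 0.8, tolerance = 1e-12)
  expect_equal(comb_raw$sigma, sd(c(0.75, 0.85, 0.8)), tolerance = 1e-12)
  expect_identical(comb_raw$n_replicates, 3L)

  # degenerate cases
  single <- combine_replicates(list(free_energy(0.8, 0.2)))
  expect_identical(single$value, 0.8)
  same <- combine_replicates(list(free_energy(1.1), free_energy(1.1),
                                  free_energy(1.1)))
  expect_identical(same$value, 1.1)
  expect_identical(same$sigma, 0)
  expect_error(combine_replicates(list()), "length")
})

test_that("fold change matches the printed equilibria", {
  expect_identical(fold_change(free_energy(0)), 1)
  expect_equal(fold_change(1.5, 310), 11.4, tolerance = 0.005)
  expect_equal(fold_change(1.6, 310), 13.4, tolerance = 0.005)
  expect_equal(fold_change(-1.5, 310), fold_change(1.5, 310)) # magnitude
})

test_that("integral-error propagation: delta method vs Monte-Carlo", {
  sp <- canonical_sample(dg_fw = 0.8, snr = 30, seed = 41)
  tab <- assignment_preset("5FW-W63")
  ints <- assign_species_integrals(fit_lorentzians(sp, tab), tab)
  s_cov <- propagate_integral_errors(ints, method = "covariance")
  s_mc <- propagate_integral_errors(ints, method = "monte_carlo",
                                    seed = 4, n_draws = 4000)
  expect_gt(s_cov, 0)
  expect_lt(abs(s_mc / s_cov - 1), 0.2)

  # zero uncertainty in, zero out
  ints0 <- structure(list(I_A_het = 0.6, I_B_het = 0.2, sigma_A_het = 0,
                          sigma_B_het = 0, cov_Bhet_Ahet = 0,
                          heterodimer_absent = FALSE),
                     class = "species_integrals")
  expect_identical(propagate_integral_errors(ints0), 0)
})

test_that("dG uncertainty shrinks like 1/SNR", {
  tab <- assignment_preset("5FW-W63")
  sig_at <- function(snr, seed) {
    sp <- canonical_sample(dg_fw = 0.8, snr = snr, seed = seed)
    propagate_integral_errors(
      assign_species_integrals(fit_lorentzians(sp, tab), tab))
  }
  s20 <- mean(vapply(1:5, function(k) sig_at(20, 500 + k), 0))
  s80 <- mean(vapply(1:5, function(k) sig_at(80, 600 + k), 0))
  expect_gt(s20, s80)
  expect_gt(s20 / s80, 2.5) # ~4 expected for a 4x SNR change
  expect_lt(s20 / s80, 6)
})

test_that("homodimer null free energy is zero with symmetric integrals", {
  ints <- list(I_A_homo = 0.5, I_B = 0.5, sigma_A_homo = 0.01,
               sigma_B = 0.01, cov_B_Ahomo = 0)
  dg <- dg_homodimer_null(ints, 310)
  expect_identical(dg$value, 0)
  expect_gt(dg$sigma, 0)
})
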