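# spectral deconvolution and species-integral assignment

test_that("noiseless fits reproduce the generator areas (oracle equivalence)", {
  for (dg in c(0.8, -0.2)) {
    sp <- canonical_sample(dg_fw = dg)
    tab <- assignment_preset("5FW-W63")
    fit <- fit_lorentzians(sp, tab)
    expect_true(fit$converged)
    ints <- assign_species_integrals(fit, tab)
    truth <- unlist(sp$metadata$true_areas)
    expect_equal(ints$I_A_homo, truth[["A_2F"]], tolerance = 1e-4)
    expect_equal(ints$I_A_het, truth[["A_1F"]], tolerance = 1e-4)
    expect_equal(ints$I_B, truth[["B_2F"]] + truth[["B_1F"]],
                 tolerance = 1e-4)
  }
})

test_that("a noiseless isolated peak is recovered essentially exactly", {
  sp <- canonical_sample(dg_fw = 0) # A_1F well resolved at -125.4
  tab <- assignment_preset("5FW-W63")
  fit <- fit_lorentzians(sp, tab)
  truth <- unlist(sp$metadata$true_areas)
  a1f <- fit$components$area[fit$components$members == "A_1F"]
  expect_equal(a1f, truth[["A_1F"]], tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("well-separated equal peaks at SNR 50 are recovered within 2%", {
  # homodimer: two peaks 1.6 ppm apart, equal areas, fwhm 0.15. The
  # heterodimer windows are parked far from any signal so this is an
  # effective two-component fit.
  sp <- canonical_sample(ratio = 1, dg_fw = 0.8, snr = 50, seed = 21)
  tab <- assignment_table(
    c(A_2F = -124.8, B_2F = -123.2, A_1F = -131, B_1F = -116),
    half_window = 0.3)
  fit <- fit_lorentzians(sp, tab)
  comp <- fit$components
  for (s in c("A_2F", "B_2F")) {
    expect_equal(comp$area[comp$members == s], 0.5, tolerance = 0.02)
  }
  # and against quadrature of the noiseless truth over the A half
  noiseless <- canonical_sample(ratio = 1, dg_fw = 0.8)
  sel <- noiseless$axis < -124
  expect_equal(comp$area[comp$members == "A_2F"],
               trapz(noiseless$axis[sel], noiseless$intensity[sel]),
               tolerance = 0.03)
})

test_that("the 1:3 three-peak scenario is recovered within 3% at SNR 50", {
  sp <- canonical_sample(dg_fw = 0.8, snr = 50, seed = 8,
                         grid = default_ppm_grid())
  tab <- assignment_preset("5FW-W63")
  fit <- fit_lorentzians(sp, tab)
  ints <- assign_species_integrals(fit, tab)
  truth <- unlist(sp$metadata$true_areas)
  expect_equal(ints$I_A_homo, truth[["A_2F"]], tolerance = 0.03)
  expect_equal(ints$I_A_het, truth[["A_1F"]], tolerance = 0.03)
  expect_equal(ints$I_B, truth[["B_2F"]] + truth[["B_1F"]],
               tolerance = 0.03)
})

test_that("fits are invariant to intensity rescaling", {
  sp <- canonical_sample(dg_fw = 0.8, snr = 50, seed = 13)
  tab <- assignment_preset("5FW-W63")
  f1 <- fit_lorentzians(sp, tab)
  sp_scaled <- fd_spectrum(sp$axis, sp$intensity * 37,
                           metadata = sp$metadata)
  f2 <- fit_lorentzians(sp_scaled, tab)
  # internal normalization makes the fit scale-equivariant up to the
  # floating-point noise of the rescaled inputs
  expect_equal(f2$components$area, f1$components$area * 37,
               tolerance = 1e-5)
  d1 <- dg_app_from_integrals(assign_species_integrals(f1, tab))
  d2 <- dg_app_from_integrals(assign_species_integrals(f2, tab))
  expect_equal(d1$value, d2$value, tolerance = 1e-5)
})

test_that("merged overlap policy reports the B group as one component", {
  sp <- canonical_sample(dg_fw = 0.8)
  tab <- assignment_preset("5FW-W63")
  fit <- fit_lorentzians(sp, tab, overlap_policy = "merged")
  expect_equal(nrow(fit$components), 3L)
  expect_true("B_2F+B_1F" %in% fit$components$group)
  # the merged single-Lorentzian total still approximates the B area
  ints <- assign_species_integrals(fit, tab)
  truth <- unlist(sp$metadata$true_areas)
  expect_equal(ints$I_B, truth[["B_2F"]] + truth[["B_1F"]],
               tolerance = 0.15)
})

test_that("species integral assignment implements the overlap correction", {
  # constructed arithmetic case: f_homo = 1/7, p_A = 1/3 (no 2F weighting;
  # the assignment only uses ratios so the normalization is free)
  fit <- minimal_fit(areas = c(0.143, 0.286, 0.714),
                     labels = c("A_2F", "A_1F", "B_2F+B_1F"),
                     members = c("A_2F", "A_1F", "B_2F+B_1F"))
  tab <- assignment_preset("5FW-W63")
  ints <- assign_species_integrals(fit, tab)
  expect_false(ints$b1f_resolved)
  expect_equal(ints$I_B_het, 0.714 - 0.143)
  expect_equal(k_corrected(ints$I_B, ints$I_A_homo, ints$I_A_het), 2.0,
               tolerance = 0.005)

  # resolved-B layout reads I_B_het directly
  fit_r <- minimal_fit(areas = c(0.143, 0.286, 0.143, 0.571),
                       labels = c("A_2F", "A_1F", "B_2F", "B_1F"),
                       members = c("A_2F", "A_1F", "B_2F", "B_1F"))
  tab_r <- assignment_preset("5FW-W63-E14Q")
  ints_r <- assign_species_integrals(fit_r, tab_r)
  expect_true(ints_r$b1f_resolved)
  expect_identical(ints_r$I_B_het, 0.571)
  # and the corrected and direct constants agree (I_B = I_B,homo + I_B,het)
  expect_equal(k_corrected(ints_r$I_B, ints_r$I_A_homo, ints_r$I_A_het),
               k_from_integrals(ints_r$I_A_het, ints_r$I_B_het),
               tolerance = 1e-12)
})

test_that("pure homodimer samples flag the heterodimer quantities absent", {
  sp <- canonical_sample(ratio = 1, dg_fw = 0.8)
  tab <- assignment_preset("5FW-W63")
  fit <- fit_lorentzians(sp, tab)
  ints <- assign_species_integrals(fit, tab)
  expect_true(ints$heterodimer_absent)
  expect_true(is.na(ints$I_A_het))
  expect_equal(ints$I_B, ints$I_A_homo, tolerance = 1e-3)
  expect_error(dg_app_from_integrals(ints), "absent")
})

test_that("inconsistent integrals (I_B < I_A,homo) are rejected", {
  fit <- minimal_fit(areas = c(0.5, 0.3, 0.2),
                     labels = c("A_2F", "A_1F", "B_2F+B_1F"),
                     members = c("A_2F", "A_1F", "B_2F+B_1F"))
  expect_error(assign_species_integrals(fit, assignment_preset("5FW-W63")),
               "negative heterodimer B intensity")
})

test_that("non-convergence is flagged, never silent", {
  sp <- canonical_sample(dg_fw = 0.8, snr = 20, seed = 2)
  tab <- assignment_preset("5FW-W63")
  fit <- fit_lorentzians(sp, tab, maxit = 1L)
  expect_false(fit$converged)
  expect_match(paste(fit$warnings, collapse = " "), "converge")
  expect_error(assign_species_integrals(fit, tab), "converge")
})

test_that("mixing consistency score is reported against the prediction", {
  sp <- canonical_sample(dg_fw = 0.8)
  tab <- assignment_preset("5FW-W63")
  d <- dimer_species_fractions(mixing_spec(0.25))
  ints <- assign_species_integrals(fit_lorentzians(sp, tab), tab,
                                   mixing = d)
  expect_lt(ints$consistency_score, 1e-3) # generator obeys the mixing model
})

test_that("covariance sigma tracks the empirical spread over noise draws", {
  # 200 seeded realizations at SNR 20; the delta-method sigma must sit
  # within a factor 2 of the replicate scatter of dG
  tab <- assignment_preset("5FW-W63")
  n <- 200L
  dgs <- sigmas <- numeric(n)
  for (k in seq_len(n)) {
    sp <- canonical_sample(dg_fw = 0.8, snr = 20, seed = 3000 + k)
    fit <- fit_lorentzians(sp, tab)
    ints <- assign_species_integrals(fit, tab)
    dgs[k] <- dg_app_from_integrals(ints)$value
    sigmas[k] <- propagate_integral_errors(ints)
  }
  emp <- sd(dgs)
  expect_gt(median(sigmas) / emp, 0.5)
  expect_lt(median(sigmas) / emp, 2)
})

test_that("contaminant components absorb nuisance peaks", {
  sp <- canonical_sample(dg_fw = 0.8)
  # inject a contaminant away from the assignment windows
  contaminated <- fd_spectrum(
    sp$axis,
    sp$intensity + lorentzian_profile(-121.0, 0.1, 0.2, sp$axis),
    metadata = sp$metadata)
  tab <- assignment_preset("5FW-W63")
  fit <- fit_lorentzians(contaminated, tab, extra_peaks = -121.0)
  ints <- assign_species_integrals(fit, tab)
  truth <- unlist(sp$metadata$true_areas)
  # species integrals unaffected by the nuisance peak
  expect_equal(ints$I_A_het, truth[["A_1F"]], tolerance = 1e-3)
  cont <- fit$components[grepl("contaminant", fit$components$group), ]
  expect_equal(cont$area, 0.2, tolerance = 1e-3)
})
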