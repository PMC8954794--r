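test_that("two-state excess Cp has the closed-form peak and conserves enthalpy", {
  Tm <- 357.31; dH <- 100
  # at T = Tm, K = 1 and the excess equals A dH^2 / (4 R Tm^2)
  expect_equal(dsc_two_state_cp(Tm, Tm, dH, A = 1),
               dH^2 / (4 * 1.98720425e-3 * Tm^2), tolerance = 1e-12)
  expect_equal(dsc_two_state_cp(Tm, Tm, dH, A = 1), 9.8539, tolerance = 1e-4)

  # baseline-free A = 1 curve: grid argmax sits at Tm within one step
  Tg <- seq(Tm - 40, Tm + 40, by = 0.1)
  cp <- dsc_two_state_cp(Tg, Tm, dH, A = 1)
  expect_lt(abs(Tg[which.max(cp)] - Tm), 0.1 + 1e-9)

  # integral of the excess over the transition equals dH (trapezoid rule)
  integ <- sum(diff(Tg) * (cp[-1] + cp[-length(cp)]) / 2)
  expect_lt(abs(integ - dH) / dH, 1e-3)

  # A = 0 leaves the pure baseline
  expect_equal(dsc_two_state_cp(Tg, Tm, dH, A = 0, baseline = c(0.5, 0.01)),
               0.5 + 0.01 * (Tg - Tm), tolerance = 1e-12)
})

test_that("DSC fitting round-trips exactly at zero noise and recovers Tm under noise", {
  truth <- ground_truth()
  tg0 <- sim_dsc_thermogram(truth, cfg = sim_config(seed = 3, noise_sd = 0))
  f0 <- fit_dsc_two_state(tg0)
  expect_true(f0$converged)
  expect_equal(f0$Tm_K, truth$dsc$Tm_K, tolerance = 1e-7)
  expect_equal(f0$dH_kcal, truth$dsc$dH_kcal, tolerance = 1e-6)
  expect_equal(f0$A, truth$dsc$A, tolerance = 1e-6)
  expect_lt(f0$fit_rms, 1e-7)

  tg1 <- sim_dsc_thermogram(truth, cfg = sim_config(seed = 3, noise_sd = 0.01))
  f1 <- fit_dsc_two_state(tg1)
  expect_lt(abs(f1$Tm_K - truth$dsc$Tm_K), 0.2)

  # monotone signal: no interior peak to fit
  flat <- thermogram(seq(300, 340, by = 1), seq(1, 2, length.out = 41))
  expect_error(fit_dsc_two_state(flat), "peak")
})

test_that("ITC forward model obeys mass action and conservation", {
  truth <- ground_truth()
  p <- truth$itc
  iso <- itc_isotherm(p$inj_vol_uL, rep(0, 24), V0_mL = p$V0_mL,
                      cell_M = p$cell_M, syringe_M = p$syringe_M)
  fwd <- itc_forward(iso, p$Kd_M, p$n, p$dH_kcal)

  V0_L <- p$V0_mL / 1000
  dil <- exp(-cumsum(p$inj_vol_uL * 1e-6) / V0_L)
  M <- p$cell_M * dil
  X <- p$syringe_M * (1 - dil)
  # quadratic-root complex equals an independent mass-action root-finder
  for (k in c(1, 5, 12, 24)) {
    expect_equal(fwd$complex_M[k],
                 mass_action_complex(M[k], X[k], p$Kd_M, p$n),
                 tolerance = 1e-10 / max(fwd$complex_M[k], 1e-10))
  }
  # mass conservation at every injection
  expect_true(all(fwd$complex_M <= pmin(p$n * M, X) + 1e-15))

  # tight-binding limit: each pre-saturation injection releases dH per
  # mole of injected ligand (to within the ~1% displacement correction)
  tight <- itc_forward(iso, 1e-15, 1.0, -10)
  mol_inj1 <- p$syringe_M * 10e-6
  expect_equal(tight$heats_ucal[1], -10 * mol_inj1 * 1e9, tolerance = 0.02)
  # post-saturation injections release (almost) nothing
  expect_lt(abs(tight$heats_ucal[24]), abs(tight$heats_ucal[1]) / 100)
})

test_that("independent-site ITC fitting round-trips and honors the tight-binding stoichiometry", {
  truth <- ground_truth()
  iso0 <- sim_itc_isotherm(truth, cfg = sim_config(seed = 4, noise_sd = 0))
  f0 <- fit_itc_independent(iso0)
  expect_true(f0$converged)
  expect_equal(f0$Kd_M, truth$itc$Kd_M, tolerance = 1e-5)
  expect_equal(f0$n, truth$itc$n, tolerance = 1e-7)
  expect_equal(f0$dH_kcal, truth$itc$dH_kcal, tolerance = 1e-7)

  # Kd -> 0: fitted n equals moles-to-saturation over moles of protein
  truth2 <- ground_truth()
  truth2$itc$Kd_M <- 1e-12
  truth2$itc$n <- 1.3
  iso_t <- sim_itc_isotherm(truth2, cfg = sim_config(seed = 4, noise_sd = 0))
  ft <- fit_itc_independent(iso_t)
  expect_lt(abs(ft$n - 1.3) / 1.3, 0.01)

  # discard_first drops the first residual but keeps the bookkeeping
  fd <- fit_itc_independent(iso0, discard_first = TRUE)
  expect_equal(fd$Kd_M, truth$itc$Kd_M, tolerance = 1e-4)

  short <- itc_isotherm(rep(10, 4), rep(0, 4), V0_mL = 1, cell_M = 5e-5,
                        syringe_M = 5e-4)
  expect_error(fit_itc_independent(short), "at least 6")
})

test_that("molar ellipticity follows the concentration/path normalization", {
  sp <- cd_data(data.frame(wavelength_nm = 228, theta_mdeg = 100),
                conc_M = 100e-6, path_cm = 0.02)
  expect_equal(cd_molar_ellipticity(sp)$data$theta_molar, 5.0e6)

  z <- cd_data(data.frame(wavelength_nm = c(210, 228), theta_mdeg = c(0, 0)),
               conc_M = 1e-4, path_cm = 0.1)
  expect_true(all(cd_molar_ellipticity(z)$data$theta_molar == 0))

  # doubling both concentration and path divides [theta] by 4
  base <- cd_molar_ellipticity(sp)$data$theta_molar
  dbl <- cd_data(sp$data, conc_M = 200e-6, path_cm = 0.04)
  expect_equal(cd_molar_ellipticity(dbl)$data$theta_molar, base / 4)

  expect_error(cd_data(sp$data, conc_M = 0, path_cm = 0.1), "conc_M")
})

test_that("melt analysis scores reversibility and recovers the transition midpoint", {
  truth <- ground_truth()
  rev <- melt_analysis(sim_cd_melt(truth, sim_config(seed = 6, noise_sd = 0)))
  expect_equal(rev$reversibility, 1.0, tolerance = 1e-9)
  expect_lt(abs(rev$midpoint_C - truth$cd_melt$midpoint_C), 1)

  # cooling stuck at the hot endpoint: nothing recovered
  irr <- melt_analysis(sim_cd_melt(truth, sim_config(seed = 6, noise_sd = 0),
                                   reversible = FALSE))
  expect_equal(irr$reversibility, 0.0, tolerance = 0.02)

  # noisy melt still recovers the midpoint within a degree
  noisy <- melt_analysis(sim_cd_melt(truth, sim_config(seed = 6,
                                                       noise_sd = 0.01)))
  expect_lt(abs(noisy$midpoint_C - truth$cd_melt$midpoint_C), 1)

  nm <- sim_cd_melt(truth, sim_config(seed = 6, noise_sd = 0))
  expect_error(melt_analysis(nm, wavelength_nm = 300), "not on the")
})
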