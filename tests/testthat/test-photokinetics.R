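test_that("closed-form photostationary state obeys its limits", {
  sys <- default_photosystem("E", phi_EZ = 0.57, phi_ZE = 0)
  expect_equal(simulate_pss(sys)$x_Z, 1)

  # equal absorptivities, equal yields -> 50:50
  lam <- wavenumber_axis(seq(250, 450, 1))
  eps <- spectrum_1d(lam, rep(1e4, length(lam)), unit = "eps")
  sys2 <- photokinetic_system(eps, eps, 0.3, 0.3, lambda_irr = 321,
                              photon_flux = 1e-6, conc0_E = 5e-5)
  expect_equal(simulate_pss(sys2)$x_Z, 0.5)

  # equal absorptivities with the measured yields 0.57 / 0.23
  sys3 <- photokinetic_system(eps, eps, 0.57, 0.23, lambda_irr = 321,
                              photon_flux = 1e-6, conc0_E = 5e-5)
  expect_equal(simulate_pss(sys3)$x_Z, 0.7125, tolerance = 1e-12)

  sys4 <- photokinetic_system(eps, eps, 0, 0, lambda_irr = 321,
                              photon_flux = 1e-6, conc0_E = 5e-5)
  expect_error(simulate_pss(sys4), "no photostationary state")
})

test_that("ODE integration conserves mass and freezes at zero flux", {
  sys <- default_photosystem("E")
  conc <- integrate_photokinetics(sys, seq(1, 2000, length.out = 40))
  tot <- rowSums(conc)
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-9)

  sys$photon_flux <- 0
  conc0 <- integrate_photokinetics(sys, c(10, 1e4))
  expect_equal(conc0[, "E"], rep(5e-5, 2), tolerance = 1e-12)
})

test_that("long-time ODE composition matches the closed-form PSS", {
  for (st in c("E", "Z")) {
    sys <- default_photosystem(st)
    conc <- integrate_photokinetics(sys, c(1, 1e5))
    x_Z <- unname(conc[2, "Z"]) / sum(conc[2, ])
    expect_equal(x_Z, simulate_pss(sys)$x_Z, tolerance = 1e-6)
  }
})

test_that("PSS is independent of initial composition and flux", {
  lam <- wavenumber_axis(seq(250, 450, 1))
  set.seed(42)
  for (i in 1:5) {
    e1 <- spectrum_1d(lam, runif(1, 0.5, 3) * 1e4 *
                        exp(-((as.numeric(lam) - runif(1, 300, 340)) / 40)^2),
                      unit = "eps")
    e2 <- spectrum_1d(lam, runif(1, 0.5, 3) * 1e4 *
                        exp(-((as.numeric(lam) - runif(1, 300, 340)) / 40)^2),
                      unit = "eps")
    phis <- runif(2, 0.05, 0.95)
    sysA <- photokinetic_system(e1, e2, phis[1], phis[2], lambda_irr = 320,
                                photon_flux = 1e-6, conc0_E = 5e-5)
    sysB <- photokinetic_system(e1, e2, phis[1], phis[2], lambda_irr = 320,
                                photon_flux = 7e-6, conc0_Z = 2e-5)
    cA <- integrate_photokinetics(sysA, c(1, 5e5))
    cB <- integrate_photokinetics(sysB, c(1, 5e5))
    pss <- simulate_pss(sysA)$x_Z
    expect_equal(unname(cA[2, "Z"]) / sum(cA[2, ]), pss, tolerance = 1e-5)
    expect_equal(unname(cB[2, "Z"]) / sum(cB[2, ]), pss, tolerance = 1e-5)
  }
})

test_that("unmixing a constructed two-component spectrum is exact", {
  sys <- default_photosystem("E")
  a <- 3.1e-5; b <- 1.7e-5
  mix <- spectrum_1d(sys$eps_E$axis,
                     a * sys$eps_E$intensity + b * sys$eps_Z$intensity,
                     unit = "OD")
  cf <- unmix_concentrations(mix, sys$eps_E, sys$eps_Z, path_l = 1)
  expect_equal(unname(cf), c(a, b), tolerance = 1e-12)
})

test_that("noiseless quantum-yield estimation is exact", {
  sys <- default_photosystem("E", phi_EZ = 0.41, phi_ZE = 0.17)
  ser <- generate_irradiation_series(sys, short_series_times(), noise_rel = 0)
  est <- estimate_pqy(ser$times, ser$spectra, sys)
  expect_equal(est$phi_EZ, 0.41, tolerance = 1e-4)
  expect_equal(est$phi_ZE, 0.17, tolerance = 1e-4)
})

test_that("quantum yields are recovered within 2 se on noisy fixtures", {
  sysE <- default_photosystem("E")
  serE <- generate_irradiation_series(sysE, short_series_times(), seed = 7)
  estE <- estimate_pqy(serE$times, serE$spectra, sysE)
  expect_lt(abs(estE$phi_EZ - 0.57), 2 * estE$se[["phi_EZ"]])

  sysZ <- default_photosystem("Z")
  serZ <- generate_irradiation_series(sysZ, short_series_times(), seed = 7)
  estZ <- estimate_pqy(serZ$times, serZ$spectra, sysZ)
  expect_lt(abs(estZ$phi_ZE - 0.23), 2 * estZ$se[["phi_ZE"]])
})

test_that("2-se intervals cover the true yields in most repeated series", {
  sys <- default_photosystem("E")
  hits <- vapply(1:25, function(s) {
    ser <- generate_irradiation_series(sys, short_series_times(), seed = s)
    est <- estimate_pqy(ser$times, ser$spectra, sys)
    abs(est$phi_EZ - 0.57) < 2 * est$se[["phi_EZ"]] &&
      abs(est$phi_ZE - 0.23) < 2 * est$se[["phi_ZE"]]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
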