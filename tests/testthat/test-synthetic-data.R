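test_that("band shapes are unit-peak with the sign kept as a constraint tag", {
  b <- band_shape(1707, 10, sign = -1)
  nu <- seq(1620, 1780, 0.1)
  prof <- eval_band(b, nu)
  expect_equal(max(prof), 1, tolerance = 1e-10)
  expect_equal(nu[which.max(prof)], 1707)
  expect_equal(b$sign, -1)
  lor <- eval_band(band_shape(1680, 40, family = "lorentzian"), nu)
  expect_equal(max(lor), 1, tolerance = 1e-10)
  # half maximum at center +/- fwhm/2
  expect_equal(eval_band(b, 1707 + 5), 0.5, tolerance = 1e-12)
  expect_error(band_shape(1700, -3), "fwhm")
})

test_that("component kinetics have the contracted endpoints", {
  gsb <- component_kinetics("gsb_recovery", tau = 9.05, amplitude = 1,
                            residual_fraction = 0.49)
  expect_equal(eval_kinetics(gsb, 0), -1)
  expect_equal(eval_kinetics(gsb, 1e6), -(1 - 0.49), tolerance = 1e-12)
  expect_equal(eval_kinetics(gsb, -0.5), 0)
  rise <- component_kinetics("rise", tau = 18.9, amplitude = 0.45)
  expect_equal(eval_kinetics(rise, 0), 0)
  expect_equal(eval_kinetics(rise, 1e6), 0.45, tolerance = 1e-12)
  expect_error(component_kinetics("decay", 5, 1, residual_fraction = 0.5),
               "gsb_recovery")
  expect_error(component_kinetics("gsb_recovery", 5, 1), "residual_fraction")
})

test_that("zero-amplitude noiseless fixture yields an all-zero map", {
  fx <- default_fixture("E", noise_sd = 0)
  for (k in names(fx$kinetics)) fx$kinetics[[k]]$amplitude <- 0
  m <- generate_tva_map(fx)
  expect_true(all(m$dA == 0))
})

test_that("map at t = 0 is bleach plus hot ESA only (rise starts at zero)", {
  fx <- noiseless_fixture("E")
  fx$t <- delay_axis(c(-0.5, 0, 1))
  m <- generate_tva_map(fx)
  nu <- as.numeric(fx$nu)
  expected <- -1 * eval_band(band_shape(1707, 10, 1), nu) +
    0.5 * eval_band(band_shape(1680, 40, 1), nu)
  expect_equal(m$dA[2, ], expected, tolerance = 1e-12)
  expect_true(all(m$dA[1, ] == 0))  # pre-time-zero row
})

test_that("fixture band centers sit at the measured positions", {
  for (iso in c("E", "Z")) {
    fx <- default_fixture(iso)
    centers <- vapply(fx$bands, `[[`, numeric(1), "center")
    expected <- if (iso == "E") c(1707, 1680, 1718) else c(1713, 1690, 1708)
    expect_equal(unname(centers), expected)
  }
})

test_that("seeded generation is reproducible and seed-sensitive", {
  fx <- default_fixture("E")
  m1 <- generate_tva_map(fx, seed = 11)
  m2 <- generate_tva_map(fx, seed = 11)
  m3 <- generate_tva_map(fx, seed = 12)
  expect_identical(m1$dA, m2$dA)
  expect_false(identical(m1$dA, m3$dA))
  # different seeds share the identical noiseless part
  m0 <- generate_tva_map(noiseless_fixture("E"))
  expect_lt(max(abs((m1$dA - m0$dA) - (m1$dA - m0$dA))), 1e-15)
  expect_equal(mean(m3$dA - m0$dA), 0, tolerance = 1e-3)
  expect_error(generate_tva_map(fx), "seed")
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_tva_map(default_fixture("E"), seed = 5))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("noiseless map has numerical rank 3", {
  m <- generate_tva_map(noiseless_fixture("E"))
  sv <- svd(m$dA)$d
  expect_gt(sv[3] / sv[1], 1e-6)
  expect_lt(sv[4] / sv[1], 1e-12)
})

test_that("irradiation series obeys its limiting cases", {
  sys <- default_photosystem("E")
  sys$photon_flux <- 0
  ser <- generate_irradiation_series(sys, times = c(1, 10, 100), noise_rel = 0)
  expect_equal(ser$spectra[[3]]$intensity, ser$spectra[[1]]$intensity,
               tolerance = 1e-9)

  sys2 <- default_photosystem("E", phi_EZ = 0.57, phi_ZE = 0)
  ser2 <- generate_irradiation_series(sys2, times = c(1e4, 1e5), noise_rel = 0)
  conc <- ser2$conc
  expect_lt(conc[2, "E"] / (conc[2, "E"] + conc[2, "Z"]), 1e-4)
})

test_that("long irradiation series reaches the analytic PSS", {
  sys <- default_photosystem("E")
  ser <- generate_irradiation_series(sys, times = c(10, 100, 4000),
                                     seed = 3, noise_rel = 0.01)
  pss <- simulate_pss(sys)
  cf <- unmix_concentrations(ser$spectra[[3]], sys$eps_E, sys$eps_Z,
                             sys$path_l)
  x_Z <- cf["Z"] / sum(cf)
  expect_equal(unname(x_Z), pss$x_Z, tolerance = 0.03)
})

test_that("FTIR synthesis places, scales and normalizes lines", {
  single <- line_list(1000, 7)
  s <- generate_ftir(single, scale = 1, fwhm = 4)
  pk <- find_peaks(s, min_prominence = max(s$intensity) / 2)
  expect_equal(pk$position, 1000, tolerance = 0.05)

  s2 <- generate_ftir(single, scale = 0.9879, fwhm = 4)
  pk2 <- find_peaks(s2, min_prominence = max(s2$intensity) / 2)
  expect_equal(pk2$position, 987.9, tolerance = 0.05)

  # integral of noiseless spectrum ~ summed intensities (unit-area lines)
  lines <- line_list(c(980, 1020), c(3, 4))
  sp <- generate_ftir(lines, scale = 1, fwhm = 2)
  x <- as.numeric(sp$axis)
  integral <- sum(diff(x) * (head(sp$intensity, -1) + tail(sp$intensity, -1)) / 2)
  expect_equal(integral, 7, tolerance = 7 * 0.05)

  expect_error(generate_ftir(line_list(numeric(0), numeric(0))), "empty")
})
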