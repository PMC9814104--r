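test_that("line-list scaling is linear and guarded", {
  lines <- line_list(c(1000, 1650), c(1, 2), c("a", "b"))
  expect_equal(scale_linelist(lines, 1)$frequency, lines$frequency)
  expect_equal(scale_linelist(lines, 0.9879)$frequency[1], 987.9)
  # applying a factor twice is not the same as once
  twice <- scale_linelist(scale_linelist(lines, 0.9908), 0.9908)
  once <- scale_linelist(lines, 0.9908)
  expect_false(isTRUE(all.equal(twice$frequency, once$frequency)))
  expect_error(scale_linelist(lines, 1.5), "factor")
  expect_error(scale_linelist(lines, 0), "factor")
})

test_that("peak finding refines isolated bands and ignores flat spectra", {
  s <- gauss_spectrum(1707)
  pk <- find_peaks(s, min_prominence = 0.5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position, 1707, tolerance = 0.1)

  flat <- spectrum_1d(seq(1620, 1780, 1), rep(0.2, 161), unit = "OD")
  expect_equal(nrow(find_peaks(flat, min_prominence = 0.01)), 0)
})

test_that("two equal overlapping bands merge into their midpoint peak", {
  grid <- seq(1620, 1780, 0.5)
  s <- spectrum_1d(grid,
                   gauss_spectrum(1707, grid = grid)$intensity +
                     gauss_spectrum(1713, grid = grid)$intensity,
                   unit = "OD")
  pk <- find_peaks(s, min_prominence = 0.3)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position, 1710, tolerance = 0.2)
})

test_that("band matching is greedy, bounded and tie-broken low", {
  scaled <- line_list(c(1604, 1636, 1709), c(1, 1, 1),
                      c("arC-H bend + C=C", "allylic C=C", "C=O"))
  m <- match_bands(c(1605, 1635, 1710), scaled)
  expect_equal(nrow(m$pairs), 3)
  expect_lte(max(m$pairs$delta), 1)
  expect_setequal(m$pairs$label, scaled$label)

  empty <- match_bands(c(1605, 1635), line_list(numeric(0), numeric(0)))
  expect_equal(nrow(empty$pairs), 0)
  expect_equal(empty$unmatched_peaks, c(1605, 1635))

  # two peaks equidistant from one line: lower wavenumber wins
  tie <- match_bands(c(1700, 1710), line_list(1705, 1))
  expect_equal(tie$pairs$observed, 1700)
  expect_equal(tie$unmatched_peaks, 1710)

  # beyond tolerance nothing matches
  far <- match_bands(1700, line_list(1750, 1), tol = 15)
  expect_equal(nrow(far$pairs), 0)
})

test_that("difference spectra subtract pointwise and antisymmetrically", {
  a <- gauss_spectrum(1707)
  b <- gauss_spectrum(1713)
  expect_true(all(difference_spectrum(a, a)$intensity == 0))
  d1 <- difference_spectrum(a, b)
  d2 <- difference_spectrum(b, a)
  expect_equal(d1$intensity, -d2$intensity)

  # pure E pre, 50:50 mixture post: bleach at the E band, growth at Z
  mix <- spectrum_1d(a$axis, 0.5 * a$intensity + 0.5 * b$intensity, unit = "OD")
  d <- difference_spectrum(a, mix)
  grid <- as.numeric(d$axis)
  expect_lt(d$intensity[which.min(abs(grid - 1707))], 0)
  expect_gt(d$intensity[which.min(abs(grid - 1713))], 0)

  short <- gauss_spectrum(1707, grid = seq(1620, 1700, 0.5))
  expect_error(difference_spectrum(a, short), "axis")
})

test_that("noiseless mixtures unmix exactly", {
  pe <- gauss_spectrum(1707)
  pz <- gauss_spectrum(1713)
  mix <- spectrum_1d(pe$axis, 0.43 * pe$intensity + 0.57 * pz$intensity,
                     unit = "OD")
  comp <- composition_from_spectrum(mix, pe, pz)
  expect_equal(comp$fraction_Z, 0.57, tolerance = 1e-9)
  expect_equal(composition_from_spectrum(pz, pe, pz)$fraction_Z, 1,
               tolerance = 1e-9)
  expect_error(composition_from_spectrum(mix, pe, pe), "collinear")
})

test_that("unmixing of noisy mixtures is unbiased", {
  pe <- gauss_spectrum(1707)
  pz <- gauss_spectrum(1713)
  truth <- 0.57
  clean <- 0.43 * pe$intensity + truth * pz$intensity
  set.seed(19)
  fz <- vapply(1:50, function(i) {
    noisy <- spectrum_1d(pe$axis, clean + rnorm(length(clean), sd = 0.01),
                         unit = "OD")
    composition_from_spectrum(noisy, pe, pz)$fraction_Z
  }, numeric(1))
  expect_lt(abs(mean(fz) - truth), 2 * stats::sd(fz) / sqrt(50))
})

test_that("scaling commutes with broadening", {
  lines <- line_list(c(1600, 1700), c(2, 3))
  grid <- wavenumber_axis(seq(1500, 1800, 0.5))
  a <- generate_ftir(lines, scale = 0.9879, fwhm = 8, grid = grid)
  b <- generate_ftir(scale_linelist(lines, 0.9879), scale = 1, fwhm = 8,
                     grid = grid)
  expect_lt(max(abs(a$intensity - b$intensity)), 1e-12)
})
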