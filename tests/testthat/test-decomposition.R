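test_that("default bases carry the per-isomer band centers", {
  bE <- build_basis("E")
  expect_equal(unname(vapply(bE, `[[`, numeric(1), "center")),
               c(1707, 1680, 1718))
  bZ <- build_basis("Z")
  expect_equal(unname(vapply(bZ, `[[`, numeric(1), "center")),
               c(1713, 1690, 1708))
  expect_equal(bE$gsb$sign, -1)
  expect_equal(bE$photoisomer$sign, 1)
})

test_that("basis overrides are honoured and validated", {
  b <- build_basis("E", overrides = list(gsb = list(center = 1700),
                                         vib_relax = list(family = "lorentzian")))
  expect_equal(b$gsb$center, 1700)
  expect_equal(b$vib_relax$family, "lorentzian")
  expect_error(build_basis("E", overrides = list(gsb = list(fwhm = -1))), "fwhm")
  expect_error(build_basis("E", overrides = list(nope = list(center = 1))),
               "unknown component")
})

test_that("a pure single-component map decomposes to the identity", {
  basis <- build_basis("E")
  nu <- wavenumber_axis(seq(1620, 1780, 1))
  t <- delay_axis(c(0.5, 1, 5))
  shape <- eval_band(basis$photoisomer, as.numeric(nu))
  m <- tva_map(nu, t, matrix(rep(shape, 3), nrow = 3, byrow = TRUE))
  tr <- decompose(m, basis)
  expect_equal(tr$photoisomer, rep(1, 3), tolerance = 1e-10)
  expect_equal(tr$gsb, rep(0, 3))
  expect_equal(tr$vib_relax, rep(0, 3))
  expect_lt(max(tr$rms_residual), 1e-10)
})

test_that("noiseless fixture decomposition recovers the generator traces exactly", {
  for (iso in c("E", "Z")) {
    fx <- noiseless_fixture(iso)
    m <- generate_tva_map(fx)
    tr <- decompose(m, build_basis(iso))
    truth <- component_traces(fx)
    for (comp in colnames(truth)) {
      expect_lt(max(abs(tr[[comp]] - truth[, comp])), 1e-10)
    }
  }
})

test_that("noisy decomposition stays within the least-squares error bound", {
  fx <- default_fixture("E")
  m <- generate_tva_map(fx, seed = 1)
  tr <- decompose(m, build_basis("E"))
  truth <- component_traces(fx)
  for (comp in colnames(truth)) {
    expect_lt(max(abs(tr[[comp]] - truth[, comp])), 5 * fx$noise_sd)
  }
  # reported standard errors are on the right scale
  expect_true(all(tr$se_gsb > 0))
  expect_lt(max(tr$se_gsb), 10 * fx$noise_sd)
})

test_that("sign constraints bind: bleach never positive, ESA never negative", {
  fx <- default_fixture("Z")
  m <- generate_tva_map(fx, seed = 4)
  tr <- decompose(m, build_basis("Z"))
  expect_true(all(tr$gsb <= 0))
  expect_true(all(tr$vib_relax >= 0))
  expect_true(all(tr$photoisomer >= 0))
  expect_true(all(tr$pre_t0 == (tr$t < 0)))
})

test_that("adding a basis component never increases the residual", {
  fx <- default_fixture("E")
  m <- generate_tva_map(fx, seed = 2)
  full <- build_basis("E")
  two <- full[c("gsb", "photoisomer")]
  class(two) <- "basis_set"
  tr_two <- decompose(m, two)
  tr_full <- decompose(m, full)
  expect_true(all(tr_full$rms_residual <= tr_two$rms_residual + 1e-12))
})

test_that("component order only permutes columns", {
  fx <- default_fixture("E")
  m <- generate_tva_map(fx, seed = 3)
  b <- build_basis("E")
  b_perm <- b[c("photoisomer", "gsb", "vib_relax")]
  class(b_perm) <- "basis_set"
  tr1 <- decompose(m, b)
  tr2 <- decompose(m, b_perm)
  for (comp in names(b)) {
    expect_equal(tr2[[comp]], tr1[[comp]], tolerance = 1e-12)
  }
})

test_that("degenerate bases and out-of-range centers are rejected", {
  fx <- default_fixture("E")
  m <- generate_tva_map(fx, seed = 1)
  b <- build_basis("E", overrides = list(photoisomer = list(center = 1680,
                                                            fwhm = 40)))
  expect_error(decompose(m, b), "collinear")
  b2 <- build_basis("E", overrides = list(photoisomer = list(center = 1800)))
  expect_error(decompose(m, b2), "inside the map")
})
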