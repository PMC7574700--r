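# FTIR band integration, amide I deconvolution, XRD peak fitting, Scherrer.

test_that("a unit-area Gaussian integrates to 1.000 over its window", {
  s <- forward_ftir(data.frame(center = 1030, sigma = 10, area = 1))
  expect_equal(integrate_band(s, 950, 1110), 1, tolerance = 1e-3)
})

test_that("baseline-corrected area of a Gaussian on a sloped baseline matches the closed form", {
  s <- forward_ftir(data.frame(center = 1030, sigma = 10, area = 2.5),
                    baseline = c(0.3, 0.002))
  expect_equal(integrate_band(s, 950, 1110), 2.5, tolerance = 0.01)
})

test_that("integrate_band validates its window", {
  s <- forward_ftir(data.frame(center = 1030, sigma = 10, area = 1))
  expect_error(integrate_band(s, 300, 500), "outside")
  expect_error(integrate_band(s, 1030, 1032), "narrower")
})

test_that("mineral/matrix windows recover the configured area ratio within 2%", {
  bl <- ftir_band_library(mineral_to_matrix = 3.0)
  r <- compute_ftir_params(forward_ftir(bl), fit_collagen = FALSE)
  expect_equal(r$mineral_to_matrix, 3.0, tolerance = 0.02)
})

test_that("equal 1030/1020 intensities give crystallinity exactly 1", {
  bl <- ftir_band_library(crystallinity = 1.0)
  r <- compute_ftir_params(forward_ftir(bl), fit_collagen = FALSE)
  expect_equal(r$crystallinity, 1.0, tolerance = 1e-4)
})

test_that("compositional ratios are invariant to spectrum rescaling", {
  s <- forward_ftir(ftir_band_library())
  s2 <- s
  s2$value <- s$value * 7.3
  attr(s2, "truth") <- attr(s, "truth")
  r1 <- compute_ftir_params(s, fit_collagen = FALSE)
  r2 <- compute_ftir_params(s2, fit_collagen = FALSE)
  for (k in c("mineral_to_matrix", "carbonate_to_phosphate",
              "crystallinity", "acid_phosphate"))
    expect_equal(r2[[k]], r1[[k]], tolerance = 1e-9)
  a1 <- fit_amide_I(s)
  a2 <- fit_amide_I(s2)
  expect_equal(a2$NE_xLR, a1$NE_xLR, tolerance = 1e-4)
})

test_that("amide I deconvolution recovers configured sub-band areas within 2%", {
  bl <- ftir_band_library(NE_xLR = 1.9, collagen_maturity = 2.4)
  s <- forward_ftir(bl)
  fit <- fit_amide_I(s)
  truth <- tail(bl$area, 6)
  expect_equal(unname(fit$subbands$area), truth, tolerance = 0.02)
  expect_equal(fit$NE_xLR, 1.9, tolerance = 0.02)
  expect_equal(fit$collagen_maturity, 2.4, tolerance = 0.02)
  # sum of fitted areas does not exceed 1.05x the enclosed band area
  total <- integrate_band(s, 1596, 1712)
  expect_lte(sum(fit$subbands$area), 1.05 * total)
})

test_that("second derivative has local minima at the six configured centers", {
  s <- forward_ftir(ftir_band_library())
  idx <- which(s$axis >= 1596 & s$axis <= 1712)
  x <- s$axis[idx]; y <- s$value[idx]
  d2 <- diff(y, differences = 2)        # interior second difference
  xin <- x[-c(1, length(x))]
  mins <- xin[which(d2 < c(Inf, head(d2, -1)) & d2 < c(tail(d2, -1), Inf))]
  step <- mean(diff(x))
  for (cc in c(1610, 1630, 1645, 1660, 1678, 1692))
    expect_true(min(abs(mins - cc)) <= step + 1e-9,
                label = sprintf("second-derivative minimum near %d", cc))
})

test_that("Gaussian peak fit returns FWHM = 2.3548 sigma", {
  x <- seq(20, 45, by = 0.0334)
  y <- 800 * exp(-0.5 * ((x - 26) / 0.21)^2) + 30
  s <- spectrum_oq(x, y, kind = "xrd")
  f <- fit_diffraction_peak(s, 26)
  expect_equal(f$fwhm_deg, 2 * sqrt(2 * log(2)) * 0.21, tolerance = 0.005)
})

test_that("a flat pattern raises 'peak not detected'", {
  x <- seq(20, 45, by = 0.0334)
  s <- spectrum_oq(x, rep(50, length(x)), kind = "xrd")
  expect_error(fit_diffraction_peak(s, 26), "peak not detected")
})

test_that("forward_xrd peak widths invert the Scherrer relation", {
  s <- forward_xrd(18.29, 5.18)
  tt <- attr(s, "truth")
  expect_equal(tt$fwhm26_deg, oracle_fwhm_deg(18.29, 26), tolerance = 1e-12)
  expect_equal(tt$fwhm40_deg, oracle_fwhm_deg(5.18, 40), tolerance = 1e-12)
  expect_equal(tt$fwhm26_deg, 0.4953, tolerance = 1e-3)
  expect_equal(tt$fwhm40_deg, 1.8134, tolerance = 1e-3)
  f26 <- fit_diffraction_peak(s, 26)
  expect_equal(f26$fwhm_deg, tt$fwhm26_deg, tolerance = 0.005)
})

test_that("scherrer_size matches the printed sizes and scales inversely", {
  expect_equal(scherrer_size(oracle_fwhm_deg(18.29, 26), 26), 18.29,
               tolerance = 1e-6)
  expect_equal(scherrer_size(oracle_fwhm_deg(5.18, 40), 40), 5.18,
               tolerance = 1e-6)
  s1 <- scherrer_size(0.5, 26)
  expect_equal(scherrer_size(1.0, 26), s1 / 2, tolerance = 1e-12)
})

test_that("size roundtrip through pattern synthesis and fitting holds at 1% for 2-50 nm", {
  for (L in c(2, 5, 12, 30, 50)) {
    s <- forward_xrd(L, L, amp40 = 0)       # isolated 002 peak
    f <- fit_diffraction_peak(s, 26)
    expect_equal(scherrer_size(f$fwhm_deg, f$center), L, tolerance = 0.01)
  }
  # both peaks present at study-scale sizes
  x <- analyze_xrd(forward_xrd(16.67, 5.18))
  expect_equal(x$length_nm, 16.67, tolerance = 0.01)
  expect_equal(x$width_nm, 5.18, tolerance = 0.01)
})
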