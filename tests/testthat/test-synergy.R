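test_that("fraction affected is one minus viability with clamping", {
  expect_equal(fraction_affected(c(1, 0.65, 0)), c(0, 0.35, 1))
  expect_warning(out <- fraction_affected(1.02), "clamped")
  expect_equal(out, 0)
  expect_true(is.na(fraction_affected(NA_real_)))
})

test_that("Webb CI follows the fractional product and its thresholds", {
  expect_equal(webb_ci(0.8, 0.5, 0.4), 1.0)
  expect_equal(webb_ci(0.8, 0.5, 0.2), 0.5)
  expect_true(is.na(webb_ci(0, 0.5, 0.2)))
  expect_equal(as.character(classify_ci(c(0.25, 0.5, 1, 1.7))),
               c("strong synergy", "synergy", "additive", "antagonistic"))
  # boundary: 0.3 is synergy (strict < 0.3 for strong), 0.999 still synergy
  expect_equal(as.character(classify_ci(c(0.3, 0.999))),
               c("synergy", "synergy"))
})

test_that("4PL fitting recovers noiseless parameters near-exactly", {
  d <- c(0, 1, 3, 10, 30, 100, 300)
  fa <- logistic4(d, 0, 1, e50 = 30, hill = 2)
  fit <- fit_drc(d, fa)
  expect_equal(fit$type, "logistic4")
  expect_equal(fit$e50, 30, tolerance = 1e-6)
  expect_equal(fit$hill, 2, tolerance = 1e-5)
  # inverse is the true inverse
  expect_equal(inverse_dose(fit, 0.5), 30, tolerance = 1e-5)
})

test_that("4PL fitting recovers the midpoint from noisy data", {
  d <- c(0, 1, 3, 10, 30, 100)
  set.seed(42)
  fa <- pmin(pmax(logistic4(d, 0, 1, 30, 2) +
                    rnorm(length(d), sd = 0.02), 0), 1)
  fit <- fit_drc(d, fa)
  expect_equal(fit$type, "logistic4")
  expect_lt(abs(fit$e50 - 30) / 30, 0.10)
})

test_that("degenerate and non-monotone inputs are handled gracefully", {
  fit0 <- fit_drc(c(0, 1, 10, 100), rep(0, 4))
  expect_true(fit0$inactive)
  expect_true(all(is.na(inverse_dose(fit0, 0.5))))
  expect_warning(fitnm <- fit_drc(c(0, 1, 10, 100), c(0, 0.8, 0.1, 0.9)),
                 "non-monotone|isotonic")
  expect_equal(fitnm$type, "isotonic")
})

test_that("Loewe prediction honours marginals and the sham axiom", {
  ca <- fit_drc(c(0, 1, 3, 10, 30, 100), logistic4(c(0, 1, 3, 10, 30, 100),
                                                   0, 1, 10, 1.5))
  cb <- fit_drc(c(0, 3, 10, 30, 100, 300),
                logistic4(c(0, 3, 10, 30, 100, 300), 0, 1, 60, 2))
  # single-agent marginal
  expect_equal(loewe_prediction(10, 0, ca, cb)$fa, predict(ca, 10))
  expect_equal(loewe_prediction(0, 0, ca, cb)$fa, 0)
  # sham combination: same curve, doses summing to D_C(fa0)
  fa0 <- 0.4
  D <- inverse_dose(ca, fa0)
  pred <- loewe_prediction(0.3 * D, 0.7 * D, ca, ca)
  expect_equal(pred$fa, fa0, tolerance = 1e-6)
  expect_false(pred$saturated)
})

test_that("Loewe root finding matches a dense-grid scan oracle", {
  ca <- fit_drc(c(0, 1, 3, 10, 30, 100),
                logistic4(c(0, 1, 3, 10, 30, 100), 0, 1, 10, 1.5))
  cb <- fit_drc(c(0, 3, 10, 30, 100, 300),
                logistic4(c(0, 3, 10, 30, 100, 300), 0, 1, 60, 2))
  grid_fa <- seq(1e-6, 1 - 1e-6, length.out = 20001)
  for (dd in list(c(2, 20), c(8, 40), c(30, 5), c(0.5, 200))) {
    resid <- abs(dd[1] / inverse_dose(ca, grid_fa) +
                 dd[2] / inverse_dose(cb, grid_fa) - 1)
    oracle <- grid_fa[which.min(resid)]
    pred <- loewe_prediction(dd[1], dd[2], ca, cb)
    expect_lt(abs(pred$fa - oracle), 1e-4)
  }
})

test_that("Loewe excess vanishes on sham surfaces and flags synergy sign", {
  sham <- synth_dose_matrix("loewe_additive",
                            curve_params = list(a = c(0, 1, 5, 1.5)),
                            doses_a = c(0, 0.5, 1, 2, 4, 8),
                            doses_b = c(0, 0.5, 1, 2, 4, 8))
  res <- loewe_excess_matrix(sham)
  expect_lt(max(abs(res$loewe_excess)), 1e-3)
  # a boosted surface has positive interior excess
  syn <- synth_dose_matrix("synergistic", boost = 0.8)
  res2 <- loewe_excess_matrix(syn)
  expect_true(all(res2$loewe_excess[-1, -1][
    syn$fraction_affected[-1, -1] < 0.99] > -1e-6))
  expect_gt(max(res2$loewe_excess), 0.02)
})

test_that("CI equals one on Bliss surfaces and symmetry holds on transpose", {
  m <- synth_dose_matrix("bliss")
  res <- loewe_excess_matrix(m)
  expect_lt(max(abs(res$ci[-1, -1] - 1)), 1e-9)
  # relabeling drug A <-> B transposes the CI matrix exactly
  mt <- dose_matrix(m$doses_b, m$doses_a, t(m$fraction_affected),
                    m$drug_b, m$drug_a)
  res_t <- loewe_excess_matrix(mt)
  expect_equal(unname(res_t$ci), unname(t(res$ci)))
  expect_equal(unname(res_t$loewe_excess), unname(t(res$loewe_excess)),
               tolerance = 1e-6)
})

test_that("isobologram contours respect additivity and synergy", {
  sham <- synth_dose_matrix("loewe_additive",
                            curve_params = list(a = c(0, 1, 2, 1.5)),
                            doses_a = c(0, 0.5, 1, 2, 4, 8),
                            doses_b = c(0, 0.5, 1, 2, 4, 8))
  iso <- isobologram(sham, effect_level = 0.5)
  # sham contour lies on the additivity line: dose_a + dose_b = D_C(0.5)
  d50 <- iso$line$dose_a[1]
  interior <- iso$points[iso$points$dose_a > 0 & iso$points$dose_b > 0, ]
  expect_true(nrow(interior) >= 2)
  expect_lt(max(abs(interior$dose_a + interior$dose_b - d50)) / d50, 0.12)

  syn <- synth_dose_matrix("synergistic", boost = 1,
                           curve_params = list(a = c(0, 1, 2, 1.5),
                                               b = c(0, 1, 2, 1.5)),
                           doses_a = c(0, 0.5, 1, 2, 4, 8),
                           doses_b = c(0, 0.5, 1, 2, 4, 8))
  iso_s <- isobologram(syn, effect_level = 0.5)
  a50 <- iso_s$line$dose_a[1]; b50 <- iso_s$line$dose_b[2]
  inner <- iso_s$points[iso_s$points$dose_a > 0 & iso_s$points$dose_b > 0, ]
  # interior contour points fall strictly below the additivity line
  expect_true(all(inner$dose_b < (1 - inner$dose_a / a50) * b50 + 1e-9))

  # degenerate and unreachable effect levels
  expect_true(isobologram(sham, effect_level = 0)$degenerate)
  empty <- isobologram(sham, effect_level = 0.999)
  expect_equal(nrow(empty$points), 0)
  expect_match(empty$diagnostic, "not attained")
})
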