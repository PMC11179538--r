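test_that("RMR normalization applies the oxyjoule and Q10 conventions", {
  # 1 ml O2/h at 25 degC, RQ 0.8: (16 + 5.164*0.8) J/h = 5592 muW
  expect_equal(normalize_rmr(1, "VO2_ml_per_h", 25), 5592.0, tolerance = 1e-10)
  # reference temperature: unchanged
  expect_equal(normalize_rmr(123.4, "uW", 25), 123.4)
  # 10 degC below reference: multiplied by Q10 = 1.65
  expect_equal(normalize_rmr(1, "uW", 15), 1.65)
  # VCO2 converts through the respiratory quotient
  expect_equal(normalize_rmr(0.8, "VCO2_ml_per_h", 25),
               normalize_rmr(1, "VO2_ml_per_h", 25))
  expect_error(normalize_rmr(1, "kcal", 25), "unknown RMR unit")
  expect_warning(normalize_rmr(1, "uW", 60), "temperature")
  # multiplicative in the measurement value
  x <- c(0.3, 1.7, 9)
  expect_equal(normalize_rmr(3 * x, "VO2_ml_per_h", c(10, 20, 30)),
               3 * normalize_rmr(x, "VO2_ml_per_h", c(10, 20, 30)))
})

test_that("PGLS slope reduces to OLS on a star tree and matches gls", {
  star <- validate_time_tree(ape::read.tree(text = "(A:1,B:1,C:1);"))
  fit <- pgls_slope(c(A = 0, B = 0.75, C = 1.5), c(A = 0, B = 1, C = 2), star)
  expect_equal(fit$b, 0.75, tolerance = 1e-12)
  # adding a constant to the response moves only the intercept
  fit2 <- pgls_slope(c(A = 5, B = 5.75, C = 6.5), c(A = 0, B = 1, C = 2), star)
  expect_equal(fit2$b, fit$b, tolerance = 1e-12)
  expect_equal(fit2$lna, fit$lna + 5, tolerance = 1e-12)
  expect_error(pgls_slope(c(A = 1, B = 2, C = 3), c(A = 1, B = 1, C = 1), star),
               "singular")
  # cross-check against the reference GLS implementation
  skip_if_not_installed("nlme")
  set.seed(16)
  tr <- random_time_tree(10)
  x <- setNames(rnorm(10), tr$tip.label)
  y <- 0.7 * x + setNames(rnorm(10, 0, 0.3), tr$tip.label)
  ours <- pgls_slope(y, x, tr)
  d <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label],
                  sp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, tr, form = ~sp))
  expect_equal(ours$b, unname(coef(ref)[2]), tolerance = 1e-8)
  expect_equal(ours$lna, unname(coef(ref)[1]), tolerance = 1e-8)
})

test_that("mass adjustment cancels the fitted allometry", {
  cfg <- sim_config(seed = 42, rmr_sigma = 0, temp_range = c(25, 25))
  tr <- gen_time_tree(cfg)
  tt <- gen_trait_table(tr, cfg, seed = 2)
  rn <- tt$truth$rmr_normalized[tr$tip.label]
  M <- setNames(tt$traits$mass_g, tt$traits$species)[tr$tip.label]
  # exact power law: adjusted RMR is the constant a
  adj <- adjust_rmr(rn, M, 0.75)
  expect_equal(unname(adj / exp(cfg$allometry_lna)), rep(1, 12), tolerance = 1e-10)
  expect_equal(adjust_rmr(rn, M, 0), rn)
  # defining property: the adjusted trait has no residual mass slope
  cfgN <- sim_config(seed = 43)
  ttN <- gen_trait_table(tr, cfgN, seed = 3)
  rnN <- ttN$truth$rmr_normalized[tr$tip.label]
  MN <- setNames(ttN$traits$mass_g, ttN$traits$species)[tr$tip.label]
  b_hat <- pgls_slope(log(rnN), log(MN), tr)$b
  adjN <- adjust_rmr(rnN, MN, b_hat)
  expect_lt(abs(pgls_slope(log(adjN), log(MN), tr)$b), 1e-8)
})

test_that("allometric exponent is recovered across simulated clades", {
  set.seed(17)
  hit <- 0
  for (i in 1:100) {
    tr <- random_time_tree(50)
    x <- setNames(rateshift:::bm_tips_from_increments(
      tr, rnorm(nrow(tr$edge)), 0.15, log(50)), tr$tip.label)
    noise <- setNames(rateshift:::bm_tips_from_increments(
      tr, rnorm(nrow(tr$edge)), 0.035, 0), tr$tip.label)
    y <- log(1000) + 0.75 * x + noise
    b <- pgls_slope(y, x, tr)$b
    if (b >= 0.6 && b <= 0.9) hit <- hit + 1
  }
  expect_gte(hit, 90)
})

test_that("rate-trait correlation is exact on deterministic data and calibrated", {
  cfg <- sim_config(seed = 44)
  tr <- gen_time_tree(cfg)
  set.seed(18)
  y1 <- setNames(rnorm(12), tr$tip.label)
  res <- rate_trait_correlation(y1, 2 * y1, tr)
  expect_gt(res$r, 0.99); expect_gt(res$pp, 0.99)
  expect_equal(res$classification, "positive")
  # sign equivariance
  resn <- rate_trait_correlation(y1, -2 * y1, tr)
  expect_equal(resn$r, -res$r, tolerance = 1e-12)
  expect_equal(resn$pp, res$pp)
  expect_equal(resn$classification, "negative")
  # null classification stays within the small-n calibration band
  set.seed(19)
  cls <- replicate(500, {
    a <- setNames(rateshift:::bm_tips_from_increments(
      tr, rnorm(nrow(tr$edge)), 0.05, 0), tr$tip.label)
    b <- setNames(rateshift:::bm_tips_from_increments(
      tr, rnorm(nrow(tr$edge)), 0.05, 0), tr$tip.label)
    rate_trait_correlation(a, b, tr)$classification
  })
  expect_gte(mean(cls != "none"), 0.0)
  expect_lte(mean(cls != "none"), 0.15)
})
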