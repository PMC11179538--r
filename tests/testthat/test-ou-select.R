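test_that("BM likelihood equals the closed-form MVN density", {
  # two unrelated tips, unit time: bivariate standard normal at the origin
  t2 <- validate_time_tree(ape::read.tree(text = "(A:1,B:1);"))
  y <- c(A = 0, B = 0)
  expect_equal(bm_loglik(y, t2, 0, 1), -log(2 * pi), tolerance = 1e-10)
  # mean-centering: lnL maximal at the GLS mean
  set.seed(12)
  tr <- random_time_tree(8)
  y8 <- setNames(rnorm(8), tr$tip.label)
  C <- shared_path_matrix(tr)
  mu_hat <- drop(colSums(solve(C)) %*% y8[rownames(C)] / sum(solve(C)))
  expect_gt(bm_loglik(y8, tr, mu_hat, 0.5), bm_loglik(y8, tr, mu_hat + 0.1, 0.5))
  expect_gt(bm_loglik(y8, tr, mu_hat, 0.5), bm_loglik(y8, tr, mu_hat - 0.1, 0.5))
  # direct-density oracle on random trees
  for (i in 1:20) {
    tri <- random_time_tree(sample(4:9, 1))
    yi <- setNames(rnorm(ape::Ntip(tri)), tri$tip.label)
    mu <- rnorm(1); s2 <- runif(1, 0.1, 2)
    V <- s2 * shared_path_matrix(tri)[names(yi), names(yi)]
    want <- -0.5 * (length(yi) * log(2 * pi) +
                      determinant(V)$modulus[1] +
                      drop(t(yi - mu) %*% solve(V) %*% (yi - mu)))
    expect_equal(bm_loglik(yi, tri, mu, s2), want, tolerance = 1e-8)
  }
})

test_that("OU likelihood limits collapse correctly", {
  cfg <- sim_config(seed = 31)
  tr <- gen_time_tree(cfg)
  y <- setNames(rnorm(12, 0.3), tr$tip.label)
  p1 <- paint_focal_clade(tr, character(0))
  # alpha -> 0: matches BM with the same sigma2 and mu = theta
  expect_equal(ou_loglik(y, tr, p1, 1e-8, 0.01, 0.3),
               bm_loglik(y, tr, 0.3, 0.01), tolerance = 1e-3)
  # single-regime painting: OUM and OU1 identical by construction
  pm <- paint_focal_clade(tr)
  th <- c(0.2, 0.6)
  expect_equal(ou_loglik(y, tr, p1, 0.02, 0.01, 0.2),
               ou_loglik(y, tr, structure(list(edge_regime = rep(1L, nrow(tr$edge)),
                                               root_regime = 1L, k = 1L),
                                          class = "regime_painting"),
                         0.02, 0.01, 0.2), tolerance = 1e-12)
  # large alpha: independent stationary normals around the tip regime optima
  t4 <- validate_time_tree(ape::read.tree(
    text = "((A:50,B:50):50,(C:50,D:50):50);"))
  p4 <- paint_focal_clade(t4, c("A", "B"))
  y4 <- c(A = 0.55, B = 0.62, C = 0.18, D = 0.25)
  a <- 1 # alpha * shallowest distance = 100 >> 1
  m4 <- c(A = th[2], B = th[2], C = th[1], D = th[1])
  want <- sum(dnorm(y4, m4, sqrt(0.01 / (2 * a)), log = TRUE))
  expect_equal(ou_loglik(y4, t4, p4, a, 0.01, th), want, tolerance = 1e-6)
})

test_that("model comparison respects nesting and degenerate data", {
  cfg <- sim_config(seed = 32)
  tr <- gen_time_tree(cfg)
  pm <- paint_focal_clade(tr)
  set.seed(2)
  for (i in 1:10) {
    y <- setNames(rnorm(12), tr$tip.label)
    cm <- compare_models(y, tr, pm)
    expect_gte(cm$oum$lnL, cm$ou1$lnL - 1e-6)
    expect_gte(cm$oum$lnL, cm$bm$lnL - 1e-3) # BM is the alpha -> 0 boundary
    expect_gte(cm$p_oum_bm, 0); expect_lte(cm$p_oum_bm, 1)
  }
  # constant trait: no OUM support
  yc <- setNames(rep(0.4, 12), tr$tip.label)
  cmc <- compare_models(yc, tr, pm)
  expect_gt(cmc$p_oum_bm, 0.9)
})

test_that("fitted BM variance equals the GLS residual formula", {
  set.seed(13)
  tr <- random_time_tree(10)
  y <- setNames(rnorm(10), tr$tip.label)
  C <- shared_path_matrix(tr)[names(y), names(y)]
  Ci <- solve(C)
  one <- rep(1, 10)
  mu <- drop(t(one) %*% Ci %*% y) / drop(t(one) %*% Ci %*% one)
  s2_gls <- drop(t(y - mu) %*% Ci %*% (y - mu)) / 10
  fit <- rateshift:::fit_bm(y, tr)
  expect_equal(fit$sigma2, s2_gls, tolerance = 1e-8)
  expect_equal(fit$mu, mu, tolerance = 1e-8)
})

test_that("planted OUM regimes are recovered and BM is not over-called", {
  cfg <- sim_config(seed = 33)
  tr <- gen_time_tree(cfg)
  pm <- paint_focal_clade(tr)
  alpha <- 2.77 / root_age(tr); s2 <- 0.02
  th <- c(0, 3 * sqrt(s2 / (2 * alpha)))
  n <- 60
  Ro <- sapply(1:n, function(i)
    10^gen_ou_traits(tr, "OUM", pm, alpha, s2, th, seed = 500 + i)[tr$tip.label])
  Rb <- sapply(1:n, function(i)
    10^gen_ou_traits(tr, "BM", pm, alpha, s2, theta = 0, seed = 900 + i)[tr$tip.label])
  rownames(Ro) <- rownames(Rb) <- tr$tip.label
  colnames(Ro) <- paste0("o", 1:n); colnames(Rb) <- paste0("b", 1:n)
  oo <- ou_select_genes(Ro, tr, pm)
  ob <- ou_select_genes(Rb, tr, pm)
  expect_gt(mean(oo$oum_supported), 0.4)
  expect_lt(mean(ob$oum_supported), 0.15)
})
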