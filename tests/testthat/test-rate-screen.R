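test_that("exact signed-rank p matches enumeration, with and without ties", {
  expect_equal(exact_wilcoxon_signed_rank(c(1, 2, 3)), 0.25)
  expect_equal(exact_wilcoxon_signed_rank(1:11), 2 / 2^11)
  expect_equal(exact_wilcoxon_signed_rank(-c(1, 2, 3)),
               exact_wilcoxon_signed_rank(c(1, 2, 3)))
  expect_warning(p0 <- exact_wilcoxon_signed_rank(c(0, 0)), "all differences")
  expect_equal(p0, 1)
  set.seed(3)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    d <- if (i %% 2) rnorm(n) else sample(c(-3:-1, 1:3), n, replace = TRUE)
    d <- d[d != 0]
    if (!length(d)) next
    expect_equal(exact_wilcoxon_signed_rank(d), wilcoxon_brute(d),
                 tolerance = 1e-12)
  }
  # tie-free case agrees with the reference exact test
  set.seed(4)
  for (i in 1:10) {
    d <- rnorm(sample(4:12, 1))
    expect_equal(exact_wilcoxon_signed_rank(d),
                 stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up by hand", {
  expect_equal(bh_adjust(c(0.005, 0.009, 0.05, 0.5)),
               c(0.018, 0.018, 0.05 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("fast-gene caller gates on direction and handles missing genes", {
  set.seed(5)
  R <- matrix(rlnorm(12 * 30), 12, 30,
              dimnames = list(paste0("s", 1:12), paste0("g", 1:30)))
  R["s1", ] <- apply(R, 2, min) * 0.5 # focal always slowest
  calls <- call_fast_genes(R, "s1")
  expect_equal(sum(calls$fast), 0L)
  expect_true(all(calls$median_d < 0))
  R2 <- R; R2[2, 3] <- NA
  expect_message(c2 <- call_fast_genes(R2, "s1"), "skipped")
  expect_equal(nrow(c2), 29L)
  # a strongly planted gene is called
  R3 <- R; R3["s1", 1] <- max(R3[, 1]) * 5
  c3 <- call_fast_genes(R3, "s1")
  expect_true(c3$fast[c3$gene == "g1"])
})

test_that("trend detection flags strict monotone paths and scales invariantly", {
  cfg <- sim_config(seed = 24)
  tr <- gen_time_tree(cfg)
  path <- root_to_tip_edges(tr)[["F1"]]
  nodes <- c(tr$edge[path[1], 1], tr$edge[path, 2])
  ntot <- ape::Ntip(tr) + tr$Nnode
  mk <- function(vals) {
    m <- matrix(0.1, ntot, 1, dimnames = list(NULL, "g"))
    m[nodes, 1] <- vals
    m
  }
  up <- mk(seq(0.1, 0.3, length.out = length(nodes)))
  res <- detect_trend_genes(up, tr, "F1")
  expect_true(res$trend)
  expect_equal(res$fold, 3, tolerance = 1e-12)
  wob <- mk(c(0.1, 0.3, rep(0.2, length(nodes) - 2)))
  expect_false(detect_trend_genes(wob, tr, "F1")$trend)
  # invariance to positive rescaling
  expect_equal(detect_trend_genes(up * 17, tr, "F1")$trend, res$trend)
  expect_equal(detect_trend_genes(up * 17, tr, "F1")$fold, res$fold)
  # non-strict mode tolerates equal steps
  eqm <- mk(c(0.1, rep(0.2, length(nodes) - 1)))
  expect_false(detect_trend_genes(eqm, tr, "F1")$trend)
  expect_true(detect_trend_genes(eqm, tr, "F1", strict = FALSE)$trend)
})

test_that("group comparisons reproduce hand-computed ANOVA and run ANCOVA", {
  rates <- rbind(a = c(1, 2, 3), b = c(4, 5, 6))
  gc <- group_comparisons(rates)
  expect_equal(gc$anova$F, 13.5, tolerance = 1e-10)
  expect_equal(gc$anova$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-10)
  # identical rate vectors across species: no between-group signal
  same <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  gs <- group_comparisons(same)
  expect_equal(gs$anova$F, 0, tolerance = 1e-12)
  expect_true(all(gs$tukey$p_adj > 0.999))
  # degenerate: no variance anywhere
  expect_error(group_comparisons(rbind(a = c(1, 1), b = c(1, 1))),
               "F undefined")
  # ANCOVA on a group effect with a covariate
  set.seed(6)
  anc <- data.frame(response = c(5, 6, 7, 10, 11, 12),
                    group = factor(rep(c("x", "y"), each = 3)),
                    covariate = c(1, 2, 3, 1, 2, 3))
  ga <- group_comparisons(rates, ancova = anc)
  expect_lt(ga$ancova$p, 0.01)
})
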