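test_that("time-tree generator hits the target root age, clade and seed", {
  cfg <- sim_config(seed = 1)
  tr <- gen_time_tree(cfg)
  expect_equal(ape::Ntip(tr), 12L)
  expect_equal(root_age(tr), 225.84, tolerance = 1e-6)
  expect_true(ape::is.monophyletic(tr, c("F1", "F2", "F3")))
  expect_identical(write_newick(gen_time_tree(cfg)), write_newick(tr))
  tr3 <- gen_time_tree(sim_config(seed = 2, n_taxa = 3, focal_size = 1))
  expect_equal(tr3$Nnode, 2L)
  expect_error(sim_config(n_taxa = 4, focal_size = 6), "focal clade larger")
})

test_that("rate process obeys the Brownian increment law and its limits", {
  cfg <- sim_config(seed = 2, sigma_lnr = 0, r0 = 1e-3)
  tr <- gen_time_tree(cfg)
  pr <- gen_gene_rate_process(tr, cfg, "neutral", seed = 1)
  expect_equal(pr$rate, rep(1e-3, length(pr$rate)))
  expect_equal(pr$d_e, 1e-3 * tr$edge.length, tolerance = 1e-12)
  # Monte-Carlo check of the increment variance on 1000 replicate branches
  star <- ape::stree(1000, type = "star")
  star$edge.length <- rep(50, 1000)
  star <- validate_time_tree(star)
  cfg2 <- sim_config(seed = 3, sigma_lnr = 0.05)
  pr2 <- gen_gene_rate_process(star, cfg2, "neutral", seed = 9)
  incr <- pr2$lnr[1:1000] - pr2$lnr[1001]
  expect_equal(var(incr), 0.05^2 * 50, tolerance = 0.1)
  # trend gene with zero diffusion: strictly increasing along the focal path
  cfg3 <- sim_config(seed = 4, trend_sigma = 0)
  tr3 <- gen_time_tree(cfg3)
  pr3 <- gen_gene_rate_process(tr3, cfg3, "trend", seed = 2)
  path <- root_to_tip_edges(tr3)[["F1"]]
  nodes <- c(tr3$edge[path[1], 1], tr3$edge[path, 2])
  expect_true(all(diff(pr3$lnr[nodes]) > 0))
  # the planted fold is the configured total increase
  expect_equal(pr3$rate[nodes[length(nodes)]] / pr3$rate[nodes[1]], 2.22,
               tolerance = 1e-6)
  expect_error(sim_config(sigma_lnr = -1), "sigma_lnr")
})

test_that("fast genes have elevated focal-clade rates only", {
  cfg <- sim_config(seed = 5, sigma_lnr = 0)
  tr <- gen_time_tree(cfg)
  base <- gen_gene_rate_process(tr, cfg, "neutral", seed = 3)
  fast <- gen_gene_rate_process(tr, cfg, "fast", seed = 3)
  expect_equal(fast$tip_R[c("F1", "F2", "F3")] /
                 base$tip_R[c("F1", "F2", "F3")] > 2, c(F1 = TRUE, F2 = TRUE, F3 = TRUE))
  expect_equal(fast$tip_R["S1"], base$tip_R["S1"], tolerance = 1e-12)
})

test_that("nucleotide simulator matches zero-divergence and JC expectations", {
  cfg <- sim_config(seed = 6)
  tr <- gen_time_tree(cfg)
  aln0 <- gen_alignment_nt(tr, rep(0, nrow(tr$edge)), 200, seed = 1)
  expect_true(all(apply(aln0, 2, function(col) length(unique(col)) == 1L)))
  # two-tip tree, total path 0.2 subs/site, JC: p-distance 0.1739
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  aln <- gen_alignment_nt(t2, c(0.1, 0.1), 50000, kappa = 1, seed = 2)
  p <- mean(aln["A", ] != aln["B", ])
  expect_equal(p, 0.75 * (1 - exp(-4 * 0.2 / 3)), tolerance = 0.01)
  # determinism: identical bytes under one seed
  a1 <- gen_alignment_nt(tr, rep(0.01, nrow(tr$edge)), 100, seed = 5)
  a2 <- gen_alignment_nt(tr, rep(0.01, nrow(tr$edge)), 100, seed = 5)
  expect_identical(a1, a2)
})

test_that("codon simulator emits sense codons with planted selection signal", {
  cfg <- sim_config(seed = 7)
  tr <- gen_time_tree(cfg)
  aln <- gen_alignment_codon(tr, cfg, selected = TRUE, L_codons = 60, seed = 1)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(nrow(aln))) {
    cods <- apply(matrix(aln[i, ], 3), 2, paste0, collapse = "")
    expect_false(any(cods %in% stops))
  }
  # neutral control: root-state frequencies follow the F3x4 stationary law
  cfg0 <- sim_config(seed = 8, omega0 = 1)
  alnN <- gen_alignment_codon(tr, cfg0, selected = FALSE,
                              branch_subs = rep(0, nrow(tr$edge)),
                              L_codons = 5000, seed = 2)
  pi <- f3x4_frequencies(matrix(c(0.30, 0.20, 0.25, 0.25,
                                  0.25, 0.30, 0.20, 0.25,
                                  0.20, 0.25, 0.30, 0.25), 3, 4, byrow = TRUE))
  cods <- apply(matrix(alnN[1, ], 3), 2, paste0, collapse = "")
  obs <- table(factor(cods, levels = sense_codons()))
  expect_gt(chisq.test(obs, p = pi)$p.value, 0.01)
  # counting oracle on 4 taxa: extreme foreground omega inflates the
  # nonsynonymous share of foreground-lineage differences
  t4 <- validate_time_tree(ape::read.tree(text = "((F1:30,S1:30):70,(S2:50,S3:50):50);"))
  cfg9 <- sim_config(seed = 9, omega2 = 999, pos_site_frac = 0.5)
  fg <- match(match("F1", t4$tip.label), t4$edge[, 2])
  bl <- t4$edge.length / 100 # ~1 subs/codon foreground
  gc <- Biostrings::GENETIC_CODE
  ns_ratio <- function(a) {
    cod <- function(r) apply(matrix(a[r, ], 3), 2, paste0, collapse = "")
    cf <- cod("F1"); cs <- cod("S1")
    diffs <- cf != cs
    ns <- sum(gc[cf[diffs]] != gc[cs[diffs]])
    (ns + 0.5) / (sum(diffs) - ns + 0.5)
  }
  sel <- gen_alignment_codon(t4, cfg9, selected = TRUE, branch_subs = bl,
                             L_codons = 400, foreground = fg, seed = 3)
  neu <- gen_alignment_codon(t4, cfg9, selected = FALSE, branch_subs = bl,
                             L_codons = 400, foreground = fg, seed = 4)
  expect_gt(ns_ratio(sel), ns_ratio(neu))
})

test_that("trait generator obeys the allometry, Q10 and correlation laws", {
  # zero noise, all measured at the reference temperature: OLS is exact
  cfg <- sim_config(seed = 10, rmr_sigma = 0, temp_range = c(25, 25))
  tr <- gen_time_tree(cfg)
  tt <- gen_trait_table(tr, cfg, seed = 4)
  expect_true(all(tt$traits$rmr_unit %in% c("uW", "VO2_ml_per_h", "VCO2_ml_per_h")))
  rn <- normalize_rmr(tt$traits$rmr_value, tt$traits$rmr_unit,
                      tt$traits$body_temp_C)
  fit <- lm(log(rn) ~ log(tt$traits$mass_g))
  expect_equal(unname(coef(fit)[2]), 0.75, tolerance = 1e-10)
  # a species measured 10 degC below reference carries 1/Q10 of its
  # normalized value in the raw table
  cfg2 <- sim_config(seed = 11, temp_range = c(15, 15))
  tt2 <- gen_trait_table(tr, cfg2, seed = 5)
  uw <- tt2$traits$rmr_unit == "uW"
  expect_equal(tt2$traits$rmr_value[uw],
               unname(tt2$truth$rmr_normalized[tt2$traits$species[uw]]) / 1.65,
               tolerance = 1e-12)
  # correlated genes: shared-increment construction reaches the target
  # correlation at large n
  cfg3 <- sim_config(seed = 12, n_taxa = 100, focal_size = 3,
                     corr_rho = 0.9)
  tr3 <- gen_time_tree(cfg3)
  set.seed(1)
  tz <- rnorm(nrow(tr3$edge))
  tt3 <- gen_trait_table(tr3, cfg3, trait_z = tz, seed = 6)
  pr <- gen_gene_rate_process(tr3, cfg3, "correlated", shared_z = tz, seed = 7)
  r <- cor(pr$lnr[seq_len(100)][match(tr3$tip.label, tr3$tip.label)],
           log(tt3$truth$rmr_adjusted[tr3$tip.label]))
  expect_gt(r, 0.8)
  expect_lt(r, 0.97)
})

test_that("study simulation is deterministic and labels are consistent", {
  cfg <- sim_config(seed = 13, n_genes = 40)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$traits, s2$traits)
  expect_equal(sum(s1$truth$classes == "fast"), 4L)
  expect_equal(length(s1$truth$classes), 40L)
})
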