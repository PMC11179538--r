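#' Synthetic study generator
#'
#' Generates time trees, per-gene log-Brownian rate processes, nucleotide and
#' codon alignments, and trait tables with planted, labelled effects (fast
#' genes, trend genes, positively selected genes, trait-correlated genes), so
#' that every pipeline stage can be tested against known ground truth. All
#' draws are governed by a single seed; per-gene seeds are derived from it so
#' gene order never matters.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the study system: 12 taxa on an ultrametric tree of root
#' age 225.84 My with a 3-species focal clade, lognormally varying per-gene
#' rates, a subset of genes with focal-clade rate elevation, directional rate
#' trends, foreground positive selection, and traits obeying a power-law mass
#' allometry with Q10 temperature dependence.
#'
#' @param seed integer master seed.
#' @param n_taxa number of tips.
#' @param T_root root age in My.
#' @param n_genes number of genes.
#' @param gene_len_codons mean gene length in codons.
#' @param r0 root substitution rate (subs/site/My); the default puts the
#'   typical root-to-tip total near 0.18 subs/site/root-age, the cross-species
#'   average scale, with planted effects elevating the focal clade.
#' @param sigma_lnr Brownian standard deviation of ln rate per sqrt(My).
#' @param kappa HKY/GY94 transition/transversion ratio used when emitting
#'   sequences.
#' @param focal_size number of tips in the focal (monophyletic) clade.
#' @param focal_crown_frac crown age of the focal clade as a fraction of the
#'   root age (the emulated clade is deep: its crown sits at roughly 0.6 of
#'   the basal divergence).
#' @param fast_frac,fast_multiplier fraction of genes with all focal-clade
#'   branch rates multiplied, and the multiplier.
#' @param trend_frac,trend_fold,trend_sigma fraction of genes with positive
#'   ln-rate drift along the root-to-focal path, the total fold increase the
#'   drift implies over the root age, and the (reduced) BM standard deviation
#'   used for those genes.
#' @param sel_frac,omega0,omega2,pos_site_frac fraction of genes with
#'   foreground positive selection, the purifying-class omega, the foreground
#'   positive-class omega, and the fraction of positively selected sites.
#' @param allometry_b,allometry_lna RMR mass-allometry exponent and
#'   log-intercept (muW at 1 g, 25 degC).
#' @param q10_true,rq Q10 temperature coefficient and respiratory quotient
#'   used when expressing raw trait values.
#' @param rmr_sigma BM standard deviation (per sqrt(My)) of the
#'   mass-independent ln RMR noise.
#' @param corr_frac,corr_rho fraction of genes whose rate process shares
#'   Brownian increments with the RMR noise, and the increment correlation.
#' @param temp_range measurement temperature range (degC).
#' @param mass_ln_root,mass_sigma root ln body mass (g) and its BM standard
#'   deviation per sqrt(My).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_taxa = 12L, T_root = 225.84,
                       n_genes = 500L, gene_len_codons = 300L,
                       r0 = 8e-4, sigma_lnr = 0.05, kappa = 2,
                       focal_size = 3L, focal_crown_frac = 0.6,
                       fast_frac = 0.1, fast_multiplier = 3,
                       trend_frac = 0.05, trend_fold = 2.22,
                       trend_sigma = 0.01,
                       sel_frac = 0.05, omega0 = 0.2, omega2 = 4,
                       pos_site_frac = 0.1,
                       allometry_b = 0.75, allometry_lna = log(1000),
                       q10_true = 1.65, rq = 0.8, rmr_sigma = 0.03,
                       corr_frac = 0.1, corr_rho = -0.7,
                       temp_range = c(3, 28),
                       mass_ln_root = log(50), mass_sigma = 0.17) {
  fr <- c(fast_frac, trend_frac, sel_frac, corr_frac)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("planted-gene fractions must lie in [0,1] and sum to at most 1")
  if (sigma_lnr < 0 || trend_sigma < 0) stop("sigma_lnr must be >= 0")
  if (fast_multiplier <= 0) stop("rate multiplier must be > 0")
  if (omega2 < 0) stop("omega2 must be >= 0")
  if (focal_size > n_taxa) stop("focal clade larger than n_taxa")
  if (allometry_b < -2 || allometry_b > 3)
    warning("allometry exponent outside [-2, 3] is biologically implausible")
  structure(as.list(environment()), class = "sim_config")
}

# derive a bounded per-gene seed from the master seed
gene_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483587) + 1L
}

#' Generate an ultrametric time tree with a monophyletic focal clade
#'
#' The focal clade and the backbone of remaining species split at the root,
#' mirroring the deep basal divergence of the emulated system; both sides
#' are pure-birth subtrees rescaled to fixed depths (the focal crown at
#' `focal_crown_frac` of the root age, the backbone crown just below the
#' root). Focal tips are labelled `F1..Fk` (the focal species is `F1`), the
#' rest `S1..`.
#'
#' @param config a [sim_config()].
#' @return validated time tree (attribute `root_age` set).
#' @export
gen_time_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_taxa >= 3L,
            config$focal_crown_frac < 0.95)
  set.seed(config$seed)
  k <- config$focal_size
  T_ <- config$T_root
  fmt <- function(x) format(x, digits = 12, scientific = FALSE)
  n_b <- config$n_taxa - max(k, 1L)
  if (n_b < 1L) stop("need at least one non-focal species")
  bb_depth <- 0.95 * T_
  if (n_b >= 2L) {
    backbone <- ape::rphylo(n_b, birth = 0.15, death = 0)
    backbone$edge.length <- backbone$edge.length *
      (bb_depth / max(ape::node.depth.edgelength(backbone)))
    backbone$tip.label <- paste0("S", seq_len(n_b))
    bk <- sub(";\\s*$", "", ape::write.tree(backbone, digits = 12))
  } else bk <- paste0("S1:", fmt(bb_depth))
  if (k >= 2L) {
    crown <- config$focal_crown_frac * T_
    sub <- ape::rphylo(k, birth = 0.15, death = 0)
    sub$edge.length <- sub$edge.length *
      (crown / max(ape::node.depth.edgelength(sub)))
    sub$tip.label <- paste0("F", seq_len(k))
    sb <- sub(";\\s*$", "", ape::write.tree(sub, digits = 12))
    fb <- paste0(sb, ":", fmt(T_ - crown))
  } else fb <- paste0("F1:", fmt(T_))
  tr <- ape::read.tree(text = paste0("(", fb, ",", bk, ":",
                                     fmt(T_ - bb_depth), ");"))
  validate_time_tree(tr, tol = 1e-6)
}

focal_tips <- function(tree) grep("^F", tree$tip.label, value = TRUE)

# edges of the focal clade: crown edges plus the stem edge
focal_edges <- function(tree) {
  ft <- focal_tips(tree)
  if (length(ft) == 1L) return(match(match(ft, tree$tip.label), tree$edge[, 2]))
  mrca <- ape::getMRCA(tree, ft)
  desc <- c(match(ft, tree$tip.label), phangorn::Descendants(tree, mrca, "all"))
  which(tree$edge[, 2] %in% unique(c(desc, mrca)))
}

# node ids inside the focal clade (crown mrca, its descendants, tips)
focal_nodes <- function(tree) {
  ft <- focal_tips(tree)
  tip_ids <- match(ft, tree$tip.label)
  if (length(ft) == 1L) return(tip_ids)
  mrca <- ape::getMRCA(tree, ft)
  unique(c(tip_ids, mrca, phangorn::Descendants(tree, mrca, "all")))
}

#' Simulate a per-gene rate process on the tree
#'
#' The log rate evolves by Brownian motion with optional per-edge drift;
#' branch expected substitutions use the trapezoid of the endpoint rates,
#' `d_e = t_e (r_parent + r_child) / 2`. `"fast"` genes have the rates of all
#' focal-clade nodes multiplied; `"trend"` genes have positive drift on the
#' root-to-focal-tip path (with a reduced diffusion so the trend dominates).
#'
#' @param tree time tree from [gen_time_tree()].
#' @param config a [sim_config()].
#' @param gene_class one of `"neutral"`, `"fast"`, `"trend"`, `"correlated"`,
#'   `"selected"`.
#' @param shared_z optional per-edge standard-normal increments shared with
#'   the trait noise (used for `"correlated"` genes).
#' @param seed optional seed applied before drawing.
#' @return list with `lnr` (per node), `rate` (per node), `d_e` (per edge of
#'   `tree$edge`), `tip_R` (per-species root-to-tip rate, subs/site/root-age).
#' @export
gen_gene_rate_process <- function(tree, config, gene_class = "neutral",
                                  shared_z = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(config$sigma_lnr >= 0)
  ntot <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  edge <- tree$edge
  te <- tree$edge.length
  sigma <- if (gene_class == "trend") config$trend_sigma else config$sigma_lnr
  drift <- numeric(nrow(edge))
  if (gene_class == "trend") {
    path <- root_to_tip_edges(tree)[["F1"]]
    drift[path] <- log(config$trend_fold) / root_age(tree)
  }
  z <- rnorm(nrow(edge))
  if (gene_class == "correlated" && !is.null(shared_z))
    z <- config$corr_rho * shared_z + sqrt(1 - config$corr_rho^2) * z
  lnr <- numeric(ntot)
  lnr[root] <- log(config$r0)
  for (e in order_edges_preorder(tree)) {
    p <- edge[e, 1]; c <- edge[e, 2]
    lnr[c] <- lnr[p] + drift[e] * te[e] + sigma * sqrt(te[e]) * z[e]
  }
  if (gene_class == "fast")
    lnr[focal_nodes(tree)] <- lnr[focal_nodes(tree)] + log(config$fast_multiplier)
  rate <- exp(lnr)
  d_e <- te * (rate[edge[, 1]] + rate[edge[, 2]]) / 2
  paths <- root_to_tip_edges(tree)
  # subs/site/root-age: the root-to-tip path sum (path duration = one root age)
  tip_R <- vapply(paths, function(p) sum(d_e[p]), numeric(1))
  list(lnr = lnr, rate = rate, d_e = d_e, tip_R = tip_R)
}

# edge rows ordered parents-before-children
order_edges_preorder <- function(tree) {
  rev(postorder_edge_rows(tree))
}

# edge rows in postorder (children before parents), stable across calls
postorder_edge_rows <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  match(po$edge[, 2], tree$edge[, 2])
}

#' Simulate a nucleotide alignment along the tree
#'
#' Sites evolve independently under HKY from a stationary root draw; per-edge
#' expected substitutions/site are supplied, typically the `d_e` of
#' [gen_gene_rate_process()].
#'
#' @param tree time tree (topology used).
#' @param branch_subs expected substitutions/site per edge of `tree$edge`.
#' @param L alignment length (sites).
#' @param kappa,pi HKY parameters.
#' @param seed optional seed.
#' @return alignment matrix (see [as_alignment()]).
#' @export
gen_alignment_nt <- function(tree, branch_subs, L, kappa = 2,
                             pi = rep(0.25, 4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(L > 0, all(branch_subs >= 0))
  mod <- hky_q(kappa, pi)
  eig <- eig_reversible(mod$Q, mod$pi)
  ntot <- ape::Ntip(tree) + tree$Nnode
  states <- matrix(0L, ntot, L)
  root <- ape::Ntip(tree) + 1L
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = mod$pi)
  P <- pmat_cube(eig, branch_subs)
  for (e in order_edges_preorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    states[ch, ] <- evolve_states(states[p, ], P[, , e])
  }
  m <- matrix(NUC[states[seq_len(ape::Ntip(tree)), , drop = FALSE]],
              nrow = ape::Ntip(tree))
  rownames(m) <- tree$tip.label
  as_alignment(m)
}

evolve_states <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                           prob = pmax(P[s, ], 0))
  }
  out
}

#' Simulate a codon alignment, optionally with foreground positive selection
#'
#' Sites fall into purifying (omega0), neutral (omega = 1) and -- for
#' selected genes -- positive classes; positive-class sites evolve with
#' `omega2 > 1` on the focal (foreground) branches and neutrally elsewhere.
#' Only sense codons are emitted, so no stop codon can appear.
#'
#' @param tree time tree.
#' @param config a [sim_config()].
#' @param selected plant a positive-selection site class.
#' @param branch_subs expected substitutions per codon per edge; default
#'   derives from a neutral-rate process scaled by 3 sites/codon.
#' @param L_codons gene length in codons.
#' @param foreground edge indices carrying the positive class (default: the
#'   focal clade's crown and stem branches).
#' @param seed optional seed.
#' @return codon-aware alignment matrix plus attribute `site_class`.
#' @export
gen_alignment_codon <- function(tree, config, selected = FALSE,
                                branch_subs = NULL, L_codons = NULL,
                                foreground = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(L_codons)) L_codons <- config$gene_len_codons
  stopifnot(L_codons >= 50, config$omega2 >= 0)
  if (is.null(branch_subs)) {
    pr <- gen_gene_rate_process(tree, config, "neutral")
    branch_subs <- pr$d_e * 3
  }
  pi <- f3x4_frequencies(matrix(c(0.30, 0.20, 0.25, 0.25,
                                  0.25, 0.30, 0.20, 0.25,
                                  0.20, 0.25, 0.30, 0.25), 3, 4, byrow = TRUE))
  eigs <- lapply(c(config$omega0, 1, config$omega2), function(w)
    eig_reversible(build_codon_q(config$kappa, w, pi, scale = "neutral"), pi))
  fg <- if (is.null(foreground)) focal_edges(tree) else foreground
  p2 <- if (selected) config$pos_site_frac else 0
  cls_prob <- c(purifying = (1 - p2) / 2, neutral = (1 - p2) / 2, positive = p2)
  site_class <- sample(names(cls_prob), L_codons, replace = TRUE, prob = cls_prob)
  ntot <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  states <- matrix(0L, ntot, L_codons)
  states[root, ] <- sample.int(61L, L_codons, replace = TRUE, prob = pi)
  Pc <- lapply(eigs, pmat_cube, tvec = branch_subs)
  for (e in order_edges_preorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    for (cl in unique(site_class)) {
      idx <- which(site_class == cl)
      # positive sites: conserved on the background, omega2 on the foreground
      wi <- switch(cl, purifying = 1L, neutral = 2L,
                   positive = if (e %in% fg) 3L else 1L)
      states[ch, idx] <- evolve_states(states[p, idx], Pc[[wi]][, , e])
    }
  }
  cods <- sense_codons()
  ntip <- ape::Ntip(tree)
  m <- matrix("", ntip, 3L * L_codons)
  for (i in seq_len(ntip)) {
    m[i, ] <- unlist(strsplit(cods[states[i, ]], ""), use.names = FALSE)
  }
  rownames(m) <- tree$tip.label
  aln <- as_alignment(m, codon_aware = TRUE)
  attr(aln, "site_class") <- site_class
  aln
}

# standardized per-edge BM increments (trait noise backbone)
draw_edge_increments <- function(tree) rnorm(nrow(tree$edge))

# BM tip values from per-edge standardized increments
bm_tips_from_increments <- function(tree, z, sigma, x0 = 0) {
  edge <- tree$edge; te <- tree$edge.length
  ntot <- ape::Ntip(tree) + tree$Nnode
  x <- numeric(ntot); x[ape::Ntip(tree) + 1L] <- x0
  for (e in order_edges_preorder(tree))
    x[edge[e, 2]] <- x[edge[e, 1]] + sigma * sqrt(te[e]) * z[e]
  x[seq_len(ape::Ntip(tree))]
}

#' Simulate the species trait table
#'
#' Body mass evolves by Brownian motion on the tree; resting metabolic rate
#' obeys `RMR = a * M^b` with multiplicative Brownian noise, is expressed at a
#' per-species measurement temperature through the true Q10, and is reported
#' in rotating units (muW, VO2 ml/h, VCO2 ml/h) exactly as heterogeneous
#' literature compilations are.
#'
#' @param tree time tree.
#' @param config a [sim_config()].
#' @param trait_z per-edge standardized increments for the RMR noise
#'   (shared with correlated genes); drawn fresh when `NULL`.
#' @param seed optional seed.
#' @return list with `traits` (data.frame: species, rmr_value, rmr_unit,
#'   body_temp_C, mass_g) and `truth` (true b, ln a, Q10, per-species
#'   normalized and adjusted RMR).
#' @export
gen_trait_table <- function(tree, config, trait_z = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  if (is.null(trait_z)) trait_z <- draw_edge_increments(tree)
  lnM <- bm_tips_from_increments(tree, draw_edge_increments(tree),
                                 config$mass_sigma, config$mass_ln_root)
  noise <- bm_tips_from_increments(tree, trait_z, config$rmr_sigma, 0)
  ln_rmr_norm <- config$allometry_lna + config$allometry_b * lnM + noise
  t_meas <- runif(ntip, config$temp_range[1], config$temp_range[2])
  # de-normalize: value actually measured at t_meas
  rmr_uw_at_t <- exp(ln_rmr_norm) / config$q10_true^((25 - t_meas) / 10)
  units <- rep(c("uW", "VO2_ml_per_h", "VCO2_ml_per_h"), length.out = ntip)
  oxy <- 16 + 5.164 * config$rq # J per ml O2
  raw <- ifelse(units == "uW", rmr_uw_at_t,
         ifelse(units == "VO2_ml_per_h", rmr_uw_at_t * 3600 / 1e6 / oxy,
                rmr_uw_at_t * 3600 / 1e6 / oxy * config$rq))
  traits <- data.frame(species = tree$tip.label, rmr_value = raw,
                       rmr_unit = units, body_temp_C = t_meas,
                       mass_g = exp(lnM), stringsAsFactors = FALSE)
  truth <- list(b = config$allometry_b, lna = config$allometry_lna,
                q10 = config$q10_true,
                rmr_normalized = setNames(exp(ln_rmr_norm), tree$tip.label),
                rmr_adjusted = setNames(exp(config$allometry_lna + noise),
                                        tree$tip.label),
                ln_noise = setNames(noise, tree$tip.label))
  list(traits = traits, truth = truth)
}

#' Simulate a full labelled study
#'
#' Orchestrates tree, traits, per-gene rate processes and (optionally)
#' sequence alignments under one seed, returning the inputs every pipeline
#' stage consumes together with a ground-truth bundle.
#'
#' @param config a [sim_config()].
#' @param sequences also emit per-gene nucleotide alignments (`"nt"`), codon
#'   alignments for selected-class genes (`"codon"`), both, or none
#'   (`character(0)`, the default: rate processes only).
#' @param L_nt nucleotide alignment length when sequences are emitted.
#' @return list with `tree`, `genes` (per-gene list: class, process,
#'   alignments), `traits`, `truth` (gene labels and true parameters),
#'   `annotations` (synthetic gene-to-term map).
#' @export
simulate_study <- function(config, sequences = character(0), L_nt = 3000L) {
  tree <- gen_time_tree(config)
  set.seed(config$seed + 1L)
  trait_z <- draw_edge_increments(tree)
  tt <- gen_trait_table(tree, config, trait_z = trait_z,
                        seed = config$seed + 2L)
  n <- config$n_genes
  n_fast <- round(config$fast_frac * n)
  n_trend <- round(config$trend_frac * n)
  n_sel <- round(config$sel_frac * n)
  n_corr <- round(config$corr_frac * n)
  classes <- rep("neutral", n)
  classes[seq_len(n_fast)] <- "fast"
  if (n_trend) classes[n_fast + seq_len(n_trend)] <- "trend"
  if (n_sel) classes[n_fast + n_trend + seq_len(n_sel)] <- "selected"
  if (n_corr) classes[n_fast + n_trend + n_sel + seq_len(n_corr)] <- "correlated"
  gene_ids <- sprintf("g%04d", seq_len(n))
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    sd_i <- gene_seed(config$seed, i)
    pr <- gen_gene_rate_process(tree, config, classes[i],
                                shared_z = trait_z, seed = sd_i)
    g <- list(id = gene_ids[i], class = classes[i], process = pr)
    if ("nt" %in% sequences)
      g$aln_nt <- gen_alignment_nt(tree, pr$d_e, L_nt, kappa = config$kappa,
                                   seed = sd_i + 1L)
    if ("codon" %in% sequences)
      g$aln_codon <- gen_alignment_codon(tree, config,
                                         selected = classes[i] == "selected",
                                         branch_subs = pr$d_e * 3,
                                         seed = sd_i + 2L)
    genes[[i]] <- g
  }
  set.seed(config$seed + 3L)
  terms <- sprintf("T%03d", seq_len(40L))
  ann <- data.frame(
    gene = rep(gene_ids, times = 2L),
    term = c(sample(terms[1:20], n, TRUE), sample(terms[21:40], n, TRUE)),
    stringsAsFactors = FALSE)
  true_R <- vapply(genes, function(g) g$process$tip_R, numeric(ape::Ntip(tree)))
  colnames(true_R) <- gene_ids
  truth <- list(classes = setNames(classes, gene_ids),
                fast = gene_ids[classes == "fast"],
                trend = gene_ids[classes == "trend"],
                selected = gene_ids[classes == "selected"],
                correlated = gene_ids[classes == "correlated"],
                tip_R = true_R, trait = tt$truth)
  list(tree = tree, genes = genes, traits = tt$traits, truth = truth,
       annotations = ann, config = config)
}
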