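#' Substitution-saturation screen
#'
#' Entropy-based index of substitution saturation: the mean per-site
#' Shannon entropy (log base 2, gaps excluded per site) divided by the
#' expected entropy at full saturation for the same number of sequences.
#' The expectation uses the exact finite-sample mean of the plug-in entropy
#' of n draws from the alignment-wide base frequencies, so fully random
#' sequences score Iss close to 1. The critical value Iss.c is estimated by
#' Monte-Carlo: alignments are simulated across a divergence gradient,
#' topology recovery by neighbor-joining is scored, and Iss.c is the Iss
#' level where the fitted recovery probability crosses a threshold.
#'
#' @name saturation
NULL

#' Candidate pre-filter for the saturation screen
#'
#' @param blens ML branch lengths (subs/site) per edge.
#' @return `TRUE` when any single branch exceeds 1 substitution/site or the
#'   tree length (root-to-tip substitutions summed over the tree path mean)
#'   exceeds 2 substitutions per site.
#' @export
saturation_prefilter <- function(blens) {
  any(blens > 1) || sum(blens) > 2
}

# exact expected plug-in entropy (bits) of n iid draws from p
expected_entropy <- function(n, p) {
  p <- p[p > 0]
  sum(vapply(p, function(pi) {
    cs <- seq_len(n)
    sum(dbinom(cs, n, pi) * (-(cs / n) * log2(cs / n)))
  }, numeric(1)))
}

#' Index of substitution saturation
#'
#' @param aln alignment matrix (>= 4 sequences).
#' @return list: `iss`, per-site entropy ratios `h_ratio`, `h_fss` used per
#'   coverage level.
#' @export
compute_iss <- function(aln) {
  stopifnot(nrow(aln) >= 4)
  base_counts <- table(factor(as.vector(aln), levels = NUC))
  p <- as.numeric(base_counts)
  if (sum(p) == 0) stop("no unambiguous bases in alignment")
  p <- p / sum(p)
  hfss_cache <- new.env(parent = emptyenv())
  h_ratio <- apply(aln, 2L, function(col) {
    col <- col[col %in% NUC]
    n <- length(col)
    if (n < 2L) return(NA_real_)
    key <- as.character(n)
    if (is.null(hfss_cache[[key]]))
      hfss_cache[[key]] <- expected_entropy(n, p)
    cnt <- table(factor(col, levels = NUC))
    f <- as.numeric(cnt) / n
    f <- f[f > 0]
    h <- -sum(f * log2(f))
    if (hfss_cache[[key]] <= 0) 0 else h / hfss_cache[[key]]
  })
  h_ratio <- h_ratio[!is.na(h_ratio)]
  list(iss = mean(h_ratio), h_ratio = h_ratio)
}

sat_topology <- function(n_otu, shape = c("symmetric", "asymmetric")) {
  shape <- match.arg(shape)
  labs <- paste0("t", seq_len(n_otu))
  if (shape == "symmetric") {
    balanced <- function(n) {
      if (n == 1L) return("x")
      paste0("(", balanced(ceiling(n / 2)), ",", balanced(floor(n / 2)), ")")
    }
    tr <- ape::read.tree(text = paste0(balanced(n_otu), ";"))
    tr$tip.label <- labs
    tr$edge.length <- rep(1, nrow(tr$edge))
    # equalize tip depths
    dep <- ape::node.depth.edgelength(tr)
    pend <- match(seq_len(n_otu), tr$edge[, 2])
    tr$edge.length[pend] <- tr$edge.length[pend] + max(dep[1:n_otu]) - dep[1:n_otu]
  } else {
    # ultrametric ladder: internal nodes evenly spaced in age
    tr <- ape::multi2di(ape::stree(n_otu, type = "left", tip.label = labs))
    ages <- numeric(n_otu + tr$Nnode)
    ages[n_otu + seq_len(tr$Nnode)] <- seq(1, 1 / (n_otu - 1),
                                           length.out = tr$Nnode)
    tr$edge.length <- ages[tr$edge[, 1]] - ages[tr$edge[, 2]]
  }
  tr
}

#' Critical saturation index by recovery simulation
#'
#' @param n_otu number of sequences (subsampled to 32 when larger).
#' @param L alignment length.
#' @param topology_shape `"symmetric"` or `"asymmetric"`.
#' @param reps simulation replicates spread over the divergence gradient.
#' @param recovery_threshold recovery probability defining Iss.c.
#' @param seed optional seed.
#' @return list: `iss_c`, `se` (Monte-Carlo standard error), `sim`
#'   (data.frame of per-replicate Iss and recovery).
#' @export
critical_iss <- function(n_otu, L, topology_shape = "symmetric", reps = 200L,
                         recovery_threshold = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_otu >= 4)
  n_eff <- min(n_otu, 32L)
  if (reps < 40L) stop("reps too small to fit the recovery curve; use >= 40")
  tr <- sat_topology(n_eff, topology_shape)
  depth <- max(ape::node.depth.edgelength(tr))
  # gradient starts where internal branches carry real signal; the
  # saturation limb (recovery decaying with Iss) is what defines Iss.c
  grad <- exp(seq(log(0.05), log(3), length.out = reps))
  sim <- lapply(seq_len(reps), function(i) {
    tri <- tr
    tri$edge.length <- tr$edge.length * (grad[i] / depth)
    aln <- gen_alignment_nt(tri, tri$edge.length, L)
    iss <- compute_iss(aln)$iss
    d <- ape::dist.dna(ape::as.DNAbin(tolower(aln)), model = "JC69",
                       pairwise.deletion = TRUE)
    d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 1.5
    rec <- tryCatch(phangorn::RF.dist(ape::unroot(ape::nj(d)),
                                      ape::unroot(tri)) == 0,
                    error = function(e) FALSE)
    c(iss = iss, correct = as.numeric(rec))
  })
  sim <- as.data.frame(do.call(rbind, sim))
  # keep the decaying limb: from the Iss decile with the best recovery up
  qs <- quantile(sim$iss, seq(0, 0.9, 0.1))
  dec <- findInterval(sim$iss, qs)
  rec_by_dec <- tapply(sim$correct, dec, mean)
  start_dec <- as.integer(names(rec_by_dec)[which.max(rec_by_dec)])
  limb <- sim[dec >= start_dec, , drop = FALSE]
  fit <- suppressWarnings(glm(correct ~ iss, family = binomial(), data = limb))
  b <- coef(fit)
  if (is.na(b[2]) || b[2] >= 0) {
    # recovery never degrades over the gradient: Iss.c beyond observed range
    return(list(iss_c = max(sim$iss), se = NA_real_, sim = sim))
  }
  iss_c <- (qlogis(recovery_threshold) - b[1]) / b[2]
  vc <- summary(fit)$cov.scaled
  g <- c(-1 / b[2], -(qlogis(recovery_threshold) - b[1]) / b[2]^2)
  se <- sqrt(drop(t(g) %*% vc %*% g))
  list(iss_c = min(max(iss_c, min(limb$iss)), 1.2), se = se, sim = sim)
}

#' Saturation decision for one gene
#'
#' One-sample two-sided t-test of the per-site entropy ratios against Iss.c.
#'
#' @param iss result of [compute_iss()] (or the Iss value with `h_ratio`
#'   supplied via `h_ratio`).
#' @param iss_c critical value.
#' @param h_ratio per-site entropy ratios when `iss` is scalar.
#' @return list: `p`, `decision` in `retain`/`marginal`/`flag`.
#' @export
saturation_test <- function(iss, iss_c, h_ratio = NULL) {
  if (is.list(iss)) { h_ratio <- iss$h_ratio; iss <- iss$iss }
  L <- length(h_ratio)
  if (L < 2L) stop("need at least 2 informative sites")
  s <- sd(h_ratio)
  if (s == 0) {
    p <- if (abs(iss - iss_c) < 1e-12) 1 else 0
  } else {
    tstat <- (iss - iss_c) / (s / sqrt(L))
    p <- 2 * pt(-abs(tstat), df = L - 1L)
  }
  decision <- if (iss < iss_c && p < 0.05) "retain"
  else if (iss < iss_c || abs(iss - iss_c) < 1e-12) "marginal"
  else "flag"
  list(p = p, decision = decision, iss = iss, iss_c = iss_c)
}

#' Full saturation screen over genes
#'
#' @param blens_list per-gene ML branch lengths.
#' @param alns per-gene alignments (only candidates are scored).
#' @param iss_c critical value shared by the gene set.
#' @return data.frame: gene, candidate, iss, p, decision.
#' @export
saturation_screen <- function(blens_list, alns, iss_c) {
  genes <- names(blens_list)
  out <- lapply(genes, function(g) {
    cand <- saturation_prefilter(blens_list[[g]])
    if (!cand)
      return(data.frame(gene = g, candidate = FALSE, iss = NA_real_,
                        p = NA_real_, decision = "retain"))
    ci <- compute_iss(alns[[g]])
    stt <- saturation_test(ci, iss_c)
    data.frame(gene = g, candidate = TRUE, iss = ci$iss, p = stt$p,
               decision = stt$decision)
  })
  do.call(rbind, out)
}
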