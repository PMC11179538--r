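#' Branch-site positive selection test
#'
#' Branch-site model A: four site classes with class-specific dN/dS on the
#' foreground versus background branches (0: purifying everywhere; 1: neutral
#' everywhere; 2a: purifying background, positive foreground; 2b: neutral
#' background, positive foreground), class proportions
#' `p0, p1, p2a = (1-p0-p1) p0/(p0+p1), p2b = (1-p0-p1) p1/(p0+p1)`.
#' The alternative (`omega2 >= 1` free) is compared with the null
#' (`omega2 = 1`) by an unhalved chi-square(1) LRT; site posteriors for the
#' positive classes come from naive empirical Bayes at the MLEs; post-hoc
#' filters require at least one site with posterior > 0.5 and, when more than
#' five such sites exist, a median inter-site spacing above 10 codons.
#'
#' @name codon_selection
NULL

codon_state <- function(aln) {
  L <- ncol(aln) / 3L
  cods <- sense_codons()
  st <- matrix(0L, nrow(aln), L, dimnames = list(rownames(aln), NULL))
  for (i in seq_len(nrow(aln))) {
    cd <- paste0(aln[i, seq(1, ncol(aln), 3)], aln[i, seq(2, ncol(aln), 3)],
                 aln[i, seq(3, ncol(aln), 3)])
    m <- match(cd, cods)
    m[is.na(m)] <- 0L # gap, ambiguity or stop -> missing
    st[i, ] <- m
  }
  st
}

# per-class site log-likelihood matrix (npat x 4) at given parameters
branch_site_siteliks <- function(cp, po, fg_po, blens_po, kappa, omega0,
                                 omega2, pi, ntip, nnode) {
  eigs <- lapply(c(omega0, 1, omega2), function(w)
    eig_reversible(build_codon_q(kappa, w, pi, scale = "neutral"), pi))
  P <- lapply(eigs, pmat_cube, tvec = blens_po)
  E <- length(blens_po)
  wh <- function(bg, fg) ifelse(seq_len(E) %in% fg_po, fg, bg) # 0-based class idx
  classes <- list(c0 = wh(0L, 0L), c1 = wh(1L, 1L),
                  c2a = wh(0L, 2L), c2b = wh(1L, 2L))
  sapply(classes, function(wv)
    pruning_sitelik_mix_cpp(po$edge, ntip, nnode, P[[1]], P[[2]], P[[3]],
                            wv, cp$states, pi))
}

# mixture log-likelihood with (p0, p1) profiled out; par = (logit q, logit c)
# where q = p0 + p1, c = p0 / (p0 + p1)
profile_proportions <- function(sl, w) {
  M <- apply(sl, 1L, max)
  E <- exp(sl - M)
  nll <- function(par) {
    q <- plogis(par[1]); cc <- plogis(par[2])
    mix <- cc * (q * E[, 1] + (1 - q) * E[, 3]) +
      (1 - cc) * (q * E[, 2] + (1 - q) * E[, 4])
    -sum(w * (log(mix) + M))
  }
  starts <- list(c(qlogis(0.85), 0), c(qlogis(0.5), 0), c(qlogis(0.98), 1))
  fits <- lapply(starts, function(s0)
    nlminb(s0, nll, lower = c(-9, -9), upper = c(9, 9)))
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  q <- plogis(fit$par[1]); cc <- plogis(fit$par[2])
  list(lnL = -fit$objective,
       p = c(p0 = q * cc, p1 = q * (1 - cc),
             p2a = (1 - q) * cc, p2b = (1 - q) * (1 - cc)))
}

#' Fit the branch-site model (alternative and null) to one gene
#'
#' Relative branch lengths are estimated by nucleotide-level ML on the fixed
#' topology; a global scale is optimized with the codon-model parameters
#' under the alternative model and held fixed for the null, which
#' re-optimizes its remaining free parameters.
#'
#' @param aln codon-aware alignment matrix.
#' @param tree tree (`ape::phylo`); foreground defined by tip labels.
#' @param foreground tip label(s); the foreground branch set is the pendant
#'   branch (single tip) or the clade's crown branches plus stem.
#' @param control list: `eval_max`, `starts` (alternative-model multistarts).
#' @return `selection_fit` list: `lnL_alt`, `lnL_null`, `lrt`, `p`
#'   (unhalved chi-square df 1), MLEs, `site_post` (per-codon posterior of
#'   the positive classes), `sites` (codon indices with posterior > 0.5),
#'   `filters`, `significant`.
#' @export
branch_site_fit <- function(aln, tree, foreground,
                            control = list(eval_max = 300, starts = 2)) {
  stopifnot(isTRUE(attr(aln, "codon_aware")))
  st <- codon_state(aln) # gaps/ambiguities become missing states
  fg_edges <- foreground_edges(tree, foreground)
  if (length(fg_edges) == nrow(tree$edge))
    stop("foreground cannot include all branches")
  if (!length(fg_edges)) stop("empty foreground")
  po <- postorder_info(tree)
  fg_po <- match(fg_edges, po$rows)
  cp <- compress_patterns(st[tree$tip.label, , drop = FALSE])
  ntip <- ape::Ntip(tree); nnode <- tree$Nnode
  # stage 1: relative branch lengths from nucleotide-level ML
  nt <- ml_branch_lengths(aln, tree, model = "HKY")
  rel <- pmax(nt$blens * 3, 1e-5) # subs/codon scale
  rel <- rel / mean(rel)
  # F3x4 frequencies from the observed alignment
  pos_freq <- t(sapply(1:3, function(p) {
    b <- as.vector(aln[, seq(p, ncol(aln), 3)])
    tab <- table(factor(b, levels = NUC))
    pmax(as.numeric(tab), 1)
  }))
  pi <- f3x4_frequencies(pos_freq)

  obj <- function(par, null) {
    s <- exp(par[1]); kap <- exp(par[2]); w0 <- plogis(par[3])
    w2 <- if (null) 1 else 1 + exp(par[4])
    sl <- branch_site_siteliks(cp, po, fg_po, rel[po$rows] * s, kap, w0, w2,
                               pi, ntip, nnode)
    pp <- profile_proportions(sl, cp$w)
    list(nll = -pp$lnL, p = pp$p, sl = sl,
         pars = c(scale = s, kappa = kap, omega0 = w0, omega2 = w2))
  }
  scale0 <- mean(nt$blens * 3) # subs/codon initial scale
  opt_ctrl <- list(eval.max = control$eval_max, iter.max = 100,
                   rel.tol = 1e-5)
  lo <- c(log(scale0) - 4, log(0.1), -7, log(1e-4))
  hi <- c(log(scale0) + 4, log(50), 7, log(500))
  run_alt <- function(s0) nlminb(s0, function(p) obj(p, null = FALSE)$nll,
                                 lower = lo, upper = hi, control = opt_ctrl)
  # coarse omega2 profile picks the most promising start
  grid_w2 <- c(1.001, 2, 4, 16)
  grid_nll <- vapply(grid_w2, function(w2)
    obj(c(log(scale0), log(2), qlogis(0.3), log(w2 - 1)), null = FALSE)$nll,
    numeric(1))
  w2_best <- grid_w2[which.min(grid_nll)]
  starts <- list(c(log(scale0), log(2), qlogis(0.3), log(w2_best - 1 + 1e-4)),
                 c(log(scale0 * 1.5), log(2), qlogis(0.5), log(6)))
  nstart <- min(length(starts), max(1, control$starts))
  best <- NULL
  for (s0 in starts[seq_len(nstart)]) {
    ft <- run_alt(s0)
    if (is.null(best) || ft$objective < best$objective) best <- ft
  }
  # null: scale fixed, re-optimize kappa and omega0
  ft0 <- nlminb(best$par[2:3], function(p)
    obj(c(best$par[1], p), null = TRUE)$nll,
    lower = c(log(0.1), -7), upper = c(log(50), 7), control = opt_ctrl)
  # the null is nested in the alternative: restart the alternative from the
  # null solution if the null ever scores better
  if (ft0$objective < best$objective - 1e-9) {
    for (w2r in c(1.001, 4, 16)) {
      ft <- run_alt(c(best$par[1], ft0$par, log(w2r - 1 + 1e-4)))
      if (ft$objective < best$objective) best <- ft
    }
  }
  alt <- obj(best$par, null = FALSE)
  nul <- obj(c(best$par[1], ft0$par), null = TRUE)
  if (nul$nll < alt$nll) alt <- obj(c(best$par[1], ft0$par, log(1e-4)),
                                    null = FALSE) # collapse to the null point
  lnL_alt <- -alt$nll; lnL_null <- -nul$nll
  if (lnL_alt < lnL_null - 0.05)
    warning("alternative-model optimization fell below the null")
  # the null point lies inside the alternative's parameter space
  lnL_alt <- max(lnL_alt, lnL_null)
  lrt <- 2 * (lnL_alt - lnL_null)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  post <- neb_site_posteriors(alt$sl, alt$p)[cp$map, , drop = FALSE]
  pos <- post[, "c2a"] + post[, "c2b"]
  sites <- which(pos > 0.5)
  fl <- posthoc_filter(sites, p)
  structure(list(lnL_alt = lnL_alt, lnL_null = lnL_null, lrt = lrt, p = p,
                 mle = c(alt$pars, alt$p), site_post = pos, sites = sites,
                 filters = fl, significant = fl$pass),
            class = "selection_fit")
}

foreground_edges <- function(tree, foreground) {
  stopifnot(all(foreground %in% tree$tip.label))
  tips <- match(foreground, tree$tip.label)
  if (length(tips) == 1L) return(match(tips, tree$edge[, 2]))
  mrca <- ape::getMRCA(tree, tips)
  which(tree$edge[, 2] %in%
          unique(c(tips, mrca, phangorn::Descendants(tree, mrca, "all"))))
}

#' Naive empirical-Bayes site class posteriors
#'
#' @param sl per-pattern log-likelihood matrix, one column per class
#'   (c0, c1, c2a, c2b).
#' @param p class proportions.
#' @return matrix of posteriors (rows sum to 1).
#' @export
neb_site_posteriors <- function(sl, p) {
  M <- apply(sl, 1L, max)
  E <- exp(sl - M) * rep(p, each = nrow(sl))
  E / rowSums(E)
}

#' Post-hoc site filters for a branch-site result
#'
#' Passes when the unhalved LRT p is below `alpha`, at least one site has
#' positive-class posterior above 0.5 and, if more than five such sites
#' exist, the median gap between consecutive site indices exceeds 10 codons
#' (guards against alignment-error clusters).
#'
#' @param sites sorted codon indices with posterior > 0.5.
#' @param p unhalved LRT p-value.
#' @param alpha significance threshold.
#' @return list: `pass`, `site_count`, `median_gap` (NA when not applied).
#' @export
posthoc_filter <- function(sites, p, alpha = 0.05) {
  sites <- sort(sites)
  n <- length(sites)
  gap <- if (n > 1L) median(diff(sites)) else NA_real_
  spacing_ok <- n <= 5L || (!is.na(gap) && gap > 10)
  list(pass = (p < alpha) && n >= 1L && spacing_ok,
       site_count = n, median_gap = if (n > 5L) gap else NA_real_)
}
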