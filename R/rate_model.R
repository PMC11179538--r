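#' Per-gene substitution-rate estimation
#'
#' Two-stage estimator: (1) maximum-likelihood branch lengths on the fixed
#' topology by Felsenstein pruning under JC or HKY; (2) a Bayesian
#' log-Brownian rate process on the time tree, treating the estimated
#' per-branch substitution counts as Poisson observations with mean
#' `L * t_e * (r_parent + r_child) / 2`. Reported rates are posterior
#' medians; two independent chains enforce the convergence rule (relative
#' parameter discrepancy < 0.1, effective sample size > 300).
#'
#' @name rate_model
NULL

nuc_state <- function(ch) {
  s <- match(ch, NUC)
  s[is.na(s)] <- 0L
  s
}

# pattern-compress an alignment into integer states, weights, keeping a
# site -> pattern map
compress_patterns <- function(states) {
  key <- apply(states, 2L, paste0, collapse = ",")
  u <- !duplicated(key)
  map <- match(key, key[u])
  list(states = states[, u, drop = FALSE], w = as.vector(table(map)[as.character(seq_len(sum(u)))]),
       map = map)
}

# postorder edge matrix (parent, child) and the row permutation back to
# tree$edge order
postorder_info <- function(tree) {
  rows <- postorder_edge_rows(tree)
  list(edge = tree$edge[rows, , drop = FALSE], rows = rows)
}

#' Pruning log-likelihood of a nucleotide alignment
#'
#' @param aln alignment matrix.
#' @param tree `ape::phylo` (topology; edge order of `tree$edge`).
#' @param blens branch lengths (subs/site) per edge of `tree$edge`.
#' @param kappa,pi HKY parameters (`kappa = 1`, uniform `pi` gives JC).
#' @return total log-likelihood (attribute `site_loglik` has per-site values).
#' @export
nuc_loglik <- function(aln, tree, blens, kappa = 1, pi = rep(0.25, 4)) {
  st <- matrix(nuc_state(aln), nrow = nrow(aln))
  rownames(st) <- rownames(aln)
  po <- postorder_info(tree)
  cp <- compress_patterns(st[tree$tip.label, , drop = FALSE])
  mod <- hky_q(kappa, pi)
  eig <- eig_reversible(mod$Q, mod$pi)
  P <- pmat_cube(eig, blens[po$rows])
  sl <- pruning_sitelik_cpp(po$edge, ape::Ntip(tree), tree$Nnode, P,
                            cp$states, mod$pi)
  out <- sum(sl * cp$w)
  attr(out, "site_loglik") <- sl[cp$map]
  out
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' @param aln alignment matrix (labels must match the tips).
#' @param tree topology (`ape::phylo`).
#' @param model `"JC"` or `"HKY"`; under HKY, base frequencies are the
#'   observed frequencies and kappa is estimated by ML.
#' @return list: `blens` (per edge of `tree$edge`), `lnL`, `kappa`, `pi`,
#'   `convergence` (0 = optimizer converged).
#' @export
ml_branch_lengths <- function(aln, tree, model = c("HKY", "JC")) {
  model <- match.arg(model)
  if (anyDuplicated(rownames(aln))) stop("duplicate alignment labels")
  if (!all(tree$tip.label %in% rownames(aln)))
    stop("alignment labels do not cover the tree tips")
  st <- matrix(nuc_state(aln), nrow = nrow(aln))
  rownames(st) <- rownames(aln)
  st <- st[tree$tip.label, , drop = FALSE]
  allgap <- colSums(st > 0L) == 0L
  if (any(allgap)) {
    warning(sum(allgap), " all-gap column(s) dropped")
    st <- st[, !allgap, drop = FALSE]
  }
  cp <- compress_patterns(st)
  po <- postorder_info(tree)
  ntip <- ape::Ntip(tree)
  nedge <- nrow(tree$edge)
  if (model == "HKY") {
    tab <- tabulate(st[st > 0L], 4L)
    pi <- pmax(tab, 1) / sum(pmax(tab, 1))
  } else pi <- rep(0.25, 4)

  negll <- function(par) {
    bl <- exp(par[seq_len(nedge)])
    kap <- if (model == "HKY") exp(par[nedge + 1L]) else 1
    mod <- hky_q(kap, pi)
    eig <- eig_reversible(mod$Q, mod$pi)
    P <- pmat_cube(eig, bl[po$rows])
    sl <- pruning_sitelik_cpp(po$edge, ntip, tree$Nnode, P, cp$states, mod$pi)
    -sum(sl * cp$w)
  }
  p0 <- c(rep(log(0.05), nedge), if (model == "HKY") log(2))
  lo <- c(rep(log(1e-8), nedge), if (model == "HKY") log(0.05))
  hi <- c(rep(log(10), nedge), if (model == "HKY") log(100))
  fit <- optim(p0, negll, method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(maxit = 300, factr = 1e7))
  blens <- exp(fit$par[seq_len(nedge)])
  blens[blens < 2e-8] <- 0
  list(blens = blens, lnL = -fit$value,
       kappa = if (model == "HKY") exp(fit$par[nedge + 1L]) else 1,
       pi = pi, convergence = fit$convergence)
}

# effective sample size via initial-positive-sequence autocovariance
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(0)
  ac <- acf(x, lag.max = min(n - 1L, 600L), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

#' Fit the Poisson-observation log-Brownian rate process
#'
#' @param bhat ML branch lengths (subs/site) per edge of `tree$edge`.
#' @param tree validated time tree.
#' @param L alignment length used for `bhat` (sets the Poisson exposure).
#' @param n_iter,n_chains,burn_frac,thin MCMC settings.
#' @param seed optional seed.
#' @return `rate_process_fit` list: `rate` (posterior-median instant rate per
#'   node), `sigma2` (posterior median of the ln-rate BM variance per My),
#'   `sigma2_ci90`, `d_e` (posterior-median branch expected substitutions),
#'   `tip_R` (per-species root-to-tip rates, subs/site/root-age),
#'   `diagnostics` (min ESS, max between-chain discrepancy, `converged`).
#' @export
fit_rate_process <- function(bhat, tree, L, n_iter = 20000L, n_chains = 2L,
                             burn_frac = 0.25, thin = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- validate_time_tree(tree)
  edge <- tree$edge; te <- tree$edge.length
  ntot <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  counts <- as.integer(round(bhat * L))
  offs <- L * te
  r_guess <- max(sum(bhat) / sum(te), 1e-8)
  burn <- as.integer(burn_frac * n_iter)
  chains <- lapply(seq_len(n_chains), function(ch) {
    rate_mcmc_cpp(counts, offs, edge[, 1], edge[, 2], te, ntot, root,
                  mu0 = log(r_guess), s0 = 10, niter = n_iter, burn = burn,
                  thin = thin, x_init = log(r_guess) + (ch - 1) * 0.5,
                  v_init = 0.01 * ch)$samples
  })
  all <- do.call(rbind, chains)
  npar <- ncol(all)
  med <- apply(all, 2L, median)
  # two-chain rule on the scalar trace summaries (mean ln rate, ln variance):
  # |mean1 - mean2| / pooled trace sd < 0.1, the tracecomp convention
  summ <- function(x) cbind(mean_lnr = rowMeans(x[, seq_len(ntot), drop = FALSE]),
                            ln_v = log(x[, ntot + 1L]))
  disc <- 0
  if (n_chains >= 2L) {
    s1 <- summ(chains[[1]]); s2 <- summ(chains[[2]])
    ps <- sqrt((apply(s1, 2, var) + apply(s2, 2, var)) / 2)
    disc <- max(abs(colMeans(s1) - colMeans(s2)) / pmax(ps, 1e-12))
  }
  ess_all <- rowSums(vapply(chains, function(x) apply(cbind(x, summ(x)), 2L, ess),
                            numeric(npar + 2L)))
  names(ess_all) <- c(paste0("lnr_node", seq_len(ntot)), "sigma2",
                      "mean_lnr", "ln_v")
  ess_min <- min(ess_all[npar + 1:2]) # summary-statistic ESS drives the rule
  lnr <- med[seq_len(ntot)]
  rate <- exp(lnr)
  # posterior-median branch expected substitutions
  dmat <- te * t(exp(all[, edge[, 1]]) + exp(all[, edge[, 2]])) / 2
  d_e <- apply(dmat, 1L, median)
  paths <- root_to_tip_edges(tree)
  tip_R <- vapply(paths, function(p) sum(d_e[p]), numeric(1))
  sigma2 <- med[npar]
  structure(list(
    rate = rate, lnr = lnr, sigma2 = sigma2,
    sigma2_ci90 = unname(quantile(all[, npar], c(0.05, 0.95))),
    d_e = d_e, tip_R = tip_R,
    diagnostics = list(ess = ess_all, ess_min = ess_min, discrepancy = disc,
                       converged = (disc < 0.1 && ess_min > 300))),
    class = "rate_process_fit")
}

#' Per-species root-to-tip path rates
#'
#' `R_s` is the posterior-median expected substitutions summed along the
#' root-to-tip path. Because the path duration is exactly one root age,
#' this is the rate in substitutions per site per root age, the unit
#' species are compared in; it equals the time-weighted mean of the branch
#' rates along the path multiplied by the root age.
#'
#' @param fit a [fit_rate_process()] result.
#' @param tree the time tree it was fitted on.
#' @return named numeric vector per species.
#' @export
tip_path_rates <- function(fit, tree) {
  paths <- root_to_tip_edges(tree)
  vapply(paths, function(p) sum(fit$d_e[p]), numeric(1))
}

#' Estimate the species-by-gene rate matrix from simulated branch counts
#'
#' Process-level estimation path: per gene, Poisson substitution counts are
#' drawn from the true branch expectations (`d_e`) at alignment length `L`,
#' and the rate process is refitted from those counts. This is the estimand
#' of the two-stage pipeline without the sequence-simulation cost.
#'
#' @param study a [simulate_study()] result.
#' @param L alignment length controlling Poisson precision.
#' @param n_iter,n_chains MCMC settings per gene.
#' @return list: `R` (species x gene matrix), `fits` (per-gene
#'   `rate_process_fit`), `converged` (logical per gene).
#' @export
estimate_rate_matrix <- function(study, L = 10000L, n_iter = 20000L,
                                 n_chains = 2L) {
  tree <- study$tree
  n <- length(study$genes)
  fits <- vector("list", n)
  R <- matrix(NA_real_, ape::Ntip(tree), n,
              dimnames = list(tree$tip.label,
                              vapply(study$genes, `[[`, "", "id")))
  for (i in seq_len(n)) {
    sd_i <- gene_seed(study$config$seed, i) + 7L
    set.seed(sd_i)
    counts <- rpois(nrow(tree$edge), L * study$genes[[i]]$process$d_e)
    fit <- fit_rate_process(counts / L, tree, L, n_iter = n_iter,
                            n_chains = n_chains, seed = sd_i + 1L)
    fits[[i]] <- fit
    R[, i] <- fit$tip_R[rownames(R)]
  }
  list(R = R, fits = fits,
       converged = vapply(fits, function(f) f$diagnostics$converged, logical(1)))
}
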