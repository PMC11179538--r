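#' Brownian-motion vs Ornstein-Uhlenbeck model selection on species rates
#'
#' Per gene, the log10 per-species substitution rate is treated as an
#' evolving continuous trait. Three models are fitted by maximum likelihood:
#' BM (neutral drift: mean mu, variance sigma^2 times the shared-path
#' matrix), OU1 (single adaptive optimum theta with pull alpha), and OUM
#' (regime-specific optima painted on branches). OUM is supported for a gene
#' when it beats both BM and OU1 by likelihood-ratio tests at FDR < 0.05.
#'
#' @name ou_select
NULL

#' Paint tree branches into regimes by a focal clade
#'
#' Two regimes: every branch of the focal clade (crown plus stem) versus all
#' remaining branches; the root lies in the background regime.
#'
#' @param tree time tree.
#' @param focal tip labels of the focal clade (default: the generator's
#'   `F*` tips).
#' @return `regime_painting` list: `edge_regime` (per row of `tree$edge`),
#'   `root_regime`, `k`.
#' @export
paint_focal_clade <- function(tree, focal = NULL) {
  if (is.null(focal)) focal <- grep("^F", tree$tip.label, value = TRUE)
  reg <- rep(1L, nrow(tree$edge))
  if (length(focal)) {
    idx <- if (length(focal) == 1L)
      match(match(focal, tree$tip.label), tree$edge[, 2])
    else {
      ft <- match(focal, tree$tip.label)
      mrca <- ape::getMRCA(tree, ft)
      which(tree$edge[, 2] %in%
              unique(c(ft, mrca, phangorn::Descendants(tree, mrca, "all"))))
    }
    reg[idx] <- 2L
  }
  structure(list(edge_regime = reg, root_regime = 1L,
                 k = length(unique(reg))), class = "regime_painting")
}

#' Brownian-motion log-likelihood of tip values
#'
#' Multivariate normal with mean `mu` and covariance `sigma2 * C`, `C` the
#' shared root-to-MRCA path-time matrix.
#'
#' @param y named tip values.
#' @param tree time tree.
#' @param mu,sigma2 BM parameters (`sigma2 > 0`).
#' @return log-likelihood.
#' @export
bm_loglik <- function(y, tree, mu, sigma2) {
  stopifnot(sigma2 > 0)
  C <- shared_path_matrix(tree)[names(y), names(y)]
  mvn_loglik(y, rep(mu, length(y)), sigma2 * C)
}

mvn_loglik <- function(y, m, V) {
  ch <- tryCatch(chol(V), error = function(e) {
    warning("singular covariance; ridge added")
    chol(V + diag(1e-10 * mean(diag(V)), nrow(V)))
  })
  z <- backsolve(ch, y - m, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# OU covariance (fixed-root form) and regime-weighted expectation design.
ou_structure <- function(tree, painting, alpha) {
  C <- shared_path_matrix(tree)
  T_ <- root_age(tree)
  D <- 2 * (T_ - C) # patristic time distance between tips (ultrametric)
  W <- exp(-alpha * D) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
  k <- max(painting$edge_regime)
  ages <- node_ages(tree)
  paths <- root_to_tip_edges(tree)
  X <- matrix(0, ape::Ntip(tree), k, dimnames = list(tree$tip.label, NULL))
  for (i in seq_along(paths)) {
    for (e in paths[[i]]) {
      a_p <- ages[tree$edge[e, 1]]; a_c <- ages[tree$edge[e, 2]]
      X[i, painting$edge_regime[e]] <- X[i, painting$edge_regime[e]] +
        (exp(-alpha * a_c) - exp(-alpha * a_p))
    }
    X[i, painting$root_regime] <- X[i, painting$root_regime] + exp(-alpha * T_)
  }
  list(W = W, X = X)
}

#' Ornstein-Uhlenbeck log-likelihood with regime-painted optima
#'
#' Gaussian likelihood with covariance
#' `V_ij = sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha s_ij))`
#' (`d` patristic time distance, `s` shared path time) and expectations given
#' by the alpha-weighted average of the optima along each lineage's branch
#' history, the root sitting at the root regime's optimum.
#'
#' @param y named tip values.
#' @param tree time tree.
#' @param painting a [paint_focal_clade()]-style regime painting.
#' @param alpha pull strength (> 0, per My).
#' @param sigma2 diffusion variance.
#' @param theta optima, one per regime.
#' @return log-likelihood.
#' @export
ou_loglik <- function(y, tree, painting, alpha, sigma2, theta) {
  stopifnot(alpha > 0, sigma2 > 0,
            length(theta) == max(painting$edge_regime))
  st <- ou_structure(tree, painting, alpha)
  m <- drop(st$X[names(y), , drop = FALSE] %*% theta)
  mvn_loglik(y, m, sigma2 * st$W[names(y), names(y)])
}

# ML fit of BM (closed form)
fit_bm <- function(y, tree) {
  C <- shared_path_matrix(tree)[names(y), names(y)]
  n <- length(y)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- drop(crossprod(one, Ci %*% y) / crossprod(one, Ci %*% one))
  Q <- drop(crossprod(y - mu, Ci %*% (y - mu)))
  s2 <- max(Q / n, 1e-12)
  lnL <- -0.5 * n * log(2 * pi) - 0.5 * (determinant(C)$modulus + n * log(s2)) -
    0.5 * Q / s2
  list(model = "BM", mu = mu, sigma2 = s2, lnL = as.numeric(lnL), df = 2L)
}

# profile lnL over theta, sigma2 at fixed alpha
ou_profile <- function(y, tree, painting, alpha) {
  st <- ou_structure(tree, painting, alpha)
  W <- st$W[names(y), names(y)]
  X <- st$X[names(y), , drop = FALSE]
  n <- length(y)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) return(list(lnL = -Inf))
  Xs <- backsolve(ch, X, transpose = TRUE)
  ys <- backsolve(ch, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  theta <- tryCatch(drop(solve(XtX + diag(1e-10, ncol(X)), crossprod(Xs, ys))),
                    error = function(e) rep(mean(y), ncol(X)))
  res <- ys - Xs %*% theta
  s2 <- max(drop(crossprod(res)) / n, 1e-12)
  lnL <- -0.5 * n * log(2 * pi) - sum(log(diag(ch))) - 0.5 * n * log(s2) -
    0.5 * drop(crossprod(res)) / s2
  list(lnL = lnL, alpha = alpha, sigma2 = s2, theta = theta)
}

fit_ou <- function(y, tree, painting, n_starts = 8L) {
  T_ <- root_age(tree)
  grid <- exp(seq(log(1e-4 / T_), log(50 / T_), length.out = n_starts))
  prof <- lapply(grid, function(a) ou_profile(y, tree, painting, a))
  lls <- vapply(prof, `[[`, numeric(1), "lnL")
  best <- which.max(lls)
  lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
  op <- optimize(function(la) ou_profile(y, tree, painting, exp(la))$lnL,
                 lower = log(lo), upper = log(hi), maximum = TRUE,
                 tol = 1e-6)
  fit <- ou_profile(y, tree, painting, exp(op$maximum))
  if (fit$lnL < max(lls)) fit <- prof[[best]]
  k <- max(painting$edge_regime)
  c(fit, list(model = if (k == 1L) "OU1" else "OUM", df = 2L + k))
}

#' Fit BM, OU1 and OUM to one gene and test OUM support
#'
#' @param y named per-species values (log10 rates).
#' @param tree time tree.
#' @param painting multi-regime painting (k >= 2) for OUM.
#' @return list with the three fits, LRT p-values (`p_oum_bm`, `p_oum_ou1`;
#'   chi-square with df = parameter difference).
#' @export
compare_models <- function(y, tree, painting) {
  stopifnot(inherits(painting, "regime_painting"))
  if (var(y) < 1e-14) {
    # constant trait: every model collapses to the sigma^2 -> 0 boundary and
    # no comparison is meaningful
    bm <- fit_bm(y, tree)
    deg <- list(model = "OUM", lnL = bm$lnL, df = 2L)
    return(list(bm = bm, ou1 = deg, oum = deg, p_oum_bm = 1, p_oum_ou1 = 1))
  }
  bm <- fit_bm(y, tree)
  ou1 <- fit_ou(y, tree, paint_focal_clade(tree, character(0)))
  oum <- fit_ou(y, tree, painting)
  # nesting guard: at any alpha the multi-regime profile dominates OU1
  if (oum$lnL < ou1$lnL) {
    alt <- ou_profile(y, tree, painting, ou1$alpha)
    if (alt$lnL > oum$lnL)
      oum <- c(alt, list(model = "OUM", df = 2L + max(painting$edge_regime)))
  }
  k <- max(painting$edge_regime)
  lrt_bm <- max(0, 2 * (oum$lnL - bm$lnL))
  lrt_ou1 <- max(0, 2 * (oum$lnL - ou1$lnL))
  list(bm = bm, ou1 = ou1, oum = oum,
       p_oum_bm = pchisq(lrt_bm, df = k, lower.tail = FALSE),
       p_oum_ou1 = pchisq(lrt_ou1, df = k - 1L, lower.tail = FALSE))
}

#' Genome-wide OUM support screen
#'
#' @param rates species x gene matrix of per-species rates (natural scale;
#'   log10 is taken internally).
#' @param tree time tree.
#' @param painting regime painting (default: focal clade vs rest).
#' @param alpha FDR threshold for the verdict.
#' @return data.frame per gene: lnLs, LRT p's, BH q's, `oum_supported`.
#' @export
ou_select_genes <- function(rates, tree, painting = NULL, alpha = 0.05) {
  if (is.null(painting)) painting <- paint_focal_clade(tree)
  genes <- colnames(rates)
  res <- lapply(genes, function(g) {
    y <- log10(rates[, g])
    cm <- compare_models(y, tree, painting)
    data.frame(gene = g, lnL_bm = cm$bm$lnL, lnL_ou1 = cm$ou1$lnL,
               lnL_oum = cm$oum$lnL, p_oum_bm = cm$p_oum_bm,
               p_oum_ou1 = cm$p_oum_ou1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_oum_bm <- bh_adjust(out$p_oum_bm)
  out$q_oum_ou1 <- bh_adjust(out$p_oum_ou1)
  out$oum_supported <- out$q_oum_bm < alpha & out$q_oum_ou1 < alpha
  out
}

#' Simulate tip values under BM or (multi-regime) OU
#'
#' @param tree time tree.
#' @param model `"BM"`, `"OU1"` or `"OUM"`.
#' @param painting regime painting (for OUM).
#' @param alpha,sigma2 process parameters.
#' @param theta optima per regime (OU) or the root mean (BM).
#' @param seed optional seed.
#' @return named tip values.
#' @export
gen_ou_traits <- function(tree, model = c("OUM", "OU1", "BM"), painting = NULL,
                          alpha = 2.77 / root_age(tree), sigma2 = 0.02,
                          theta = c(0, 1), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(painting)) painting <- paint_focal_clade(tree)
  ntot <- ape::Ntip(tree) + tree$Nnode
  x <- numeric(ntot)
  root <- ape::Ntip(tree) + 1L
  if (model == "BM") {
    x[root] <- theta[1]
    for (e in order_edges_preorder(tree))
      x[tree$edge[e, 2]] <- x[tree$edge[e, 1]] +
        rnorm(1, 0, sqrt(sigma2 * tree$edge.length[e]))
  } else {
    th <- if (model == "OU1") rep(theta[1], nrow(tree$edge)) else
      theta[painting$edge_regime]
    x[root] <- theta[painting$root_regime]
    for (e in order_edges_preorder(tree)) {
      t_e <- tree$edge.length[e]
      m <- th[e] + (x[tree$edge[e, 1]] - th[e]) * exp(-alpha * t_e)
      v <- sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * t_e))
      x[tree$edge[e, 2]] <- rnorm(1, m, sqrt(v))
    }
  }
  setNames(x[seq_len(ape::Ntip(tree))], tree$tip.label)
}
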