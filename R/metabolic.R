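#' Metabolic-rate normalization, allometry and rate-trait correlation
#'
#' Raw resting metabolic rates reported as oxygen consumption, carbon-dioxide
#' production or microwatts are normalized to microwatts at 25 degC
#' (respiratory quotient 0.8, oxyjoule coefficient `16 + 5.164 RQ` J/ml O2,
#' Q10 = 1.65), the mass-allometry exponent `b` of `RMR = a M^b` is
#' estimated by phylogenetic generalized least squares under Brownian
#' covariance, and per-gene correlations between log adjusted RMR and log
#' substitution rate are obtained from a bivariate Brownian model with a
#' conjugate inverse-Wishart posterior on the 2x2 diffusion covariance.
#'
#' @name metabolic
NULL

#' Normalize a raw RMR measurement to microwatts at 25 degC
#'
#' @param raw positive measurement value.
#' @param unit `"uW"`, `"VO2_ml_per_h"` or `"VCO2_ml_per_h"`.
#' @param t_meas measurement body temperature (degC).
#' @param rq respiratory quotient (converts VCO2 to VO2 and sets the
#'   oxyjoule coefficient).
#' @param q10 temperature coefficient.
#' @param t_ref reference temperature (degC).
#' @return normalized RMR in microwatts at `t_ref`.
#' @export
normalize_rmr <- function(raw, unit, t_meas, rq = 0.8, q10 = 1.65,
                          t_ref = 25) {
  stopifnot(all(raw > 0), length(unit) %in% c(1L, length(raw)))
  unit <- rep(unit, length.out = length(raw))
  t_meas <- rep(t_meas, length.out = length(raw))
  if (any(t_meas <= -5 | t_meas >= 45))
    warning("measurement temperature outside (-5, 45) degC")
  bad <- setdiff(unit, c("uW", "VO2_ml_per_h", "VCO2_ml_per_h"))
  if (length(bad)) stop("unknown RMR unit: ", paste(bad, collapse = ","))
  oxy <- 16 + 5.164 * rq # J per ml O2
  vo2 <- ifelse(unit == "VCO2_ml_per_h", raw / rq, raw)
  uw <- ifelse(unit == "uW", raw, vo2 * oxy / 3600 * 1e6)
  uw * q10^((t_ref - t_meas) / 10)
}

#' PGLS estimate of the allometric exponent
#'
#' `ln RMR = b ln M + ln a`, generalized least squares with Brownian
#' covariance `C` (the shared path-time matrix):
#' `b_hat = (X' C^-1 X)^-1 X' C^-1 y`.
#'
#' @param ln_rmr,ln_mass named per-species vectors.
#' @param tree time tree.
#' @return list: `b`, `lna`, `se_b`, `se_lna`, `sigma2` (GLS residual
#'   variance), `fitted`.
#' @export
pgls_slope <- function(ln_rmr, ln_mass, tree) {
  sp <- tree$tip.label
  stopifnot(length(ln_rmr) >= 3, all(sp %in% names(ln_rmr)),
            all(sp %in% names(ln_mass)))
  y <- ln_rmr[sp]; x <- ln_mass[sp]
  if (var(x) == 0) stop("all masses equal: singular design")
  C <- shared_path_matrix(tree)[sp, sp]
  X <- cbind(intercept = 1, slope = x)
  ch <- chol(C)
  Xs <- backsolve(ch, X, transpose = TRUE)
  ys <- backsolve(ch, y, transpose = TRUE)
  XtXi <- solve(crossprod(Xs))
  beta <- drop(XtXi %*% crossprod(Xs, ys))
  res <- ys - Xs %*% beta
  s2 <- drop(crossprod(res)) / (length(y) - 2L)
  se <- sqrt(diag(XtXi) * s2)
  list(b = beta[2], lna = beta[1], se_b = se[2], se_lna = se[1],
       sigma2 = s2, fitted = drop(X %*% beta))
}

#' Mass-adjusted RMR
#'
#' @param rmr_norm normalized RMR (muW at 25 degC).
#' @param mass body mass (g).
#' @param b fitted allometric exponent.
#' @return `rmr_norm / mass^b`.
#' @export
adjust_rmr <- function(rmr_norm, mass, b) rmr_norm / mass^b

#' Gene-specific phylogenetic correlation between rate and adjusted RMR
#'
#' Bivariate Brownian model on the tree: the two traits (log substitution
#' rate and log adjusted RMR) share the phylogenetic covariance `C` and an
#' unknown 2x2 diffusion covariance Sigma. With the GLS mean profiled out
#' and the reference prior `|Sigma|^(-3/2)`, the posterior of Sigma is
#' inverse-Wishart IW(S, n - 1) with S the whitened residual cross-product.
#' The sign probability of the diffusion correlation
#' `r = Sigma12 / sqrt(Sigma11 Sigma22)` then has a closed form: the
#' regression coefficient `Sigma12 / Sigma22` is marginally Student-t with
#' `n - 2` degrees of freedom, and `pp = max(P(r > 0), P(r < 0))` is its
#' tail mass. A gene is classified positive or negative when pp > 0.95.
#'
#' @param y1,y2 named per-species traits (log scale).
#' @param tree time tree.
#' @param prior_df optional extra inverse-Wishart prior degrees of freedom
#'   with diagonal scale at the traits' own variances (0 = reference prior).
#' @return list: `r` (posterior point estimate of the correlation), `pp`,
#'   `classification` (`positive` / `negative` / `none` at pp > 0.95).
#' @export
rate_trait_correlation <- function(y1, y2, tree, prior_df = 0) {
  sp <- tree$tip.label
  stopifnot(all(sp %in% names(y1)), all(sp %in% names(y2)))
  Y <- cbind(y1[sp], y2[sp])
  n <- length(sp)
  C <- shared_path_matrix(tree)[sp, sp]
  ch <- chol(C)
  Ys <- backsolve(ch, Y, transpose = TRUE)
  ones <- backsolve(ch, rep(1, n), transpose = TRUE)
  mu <- drop(crossprod(ones, Ys)) / drop(crossprod(ones))
  R <- Ys - outer(drop(ones), mu)
  S <- crossprod(R)
  if (prior_df > 0) S <- S + diag(diag(S) / (n - 1), 2) * prior_df
  nu <- (n - 1) + prior_df
  r_hat <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  # beta = Sigma12/Sigma22 ~ t_{nu-1}(S12/S22, (S11 - S12^2/S22)/((nu-1) S22))
  df_t <- nu - 1
  scale2 <- max((S[1, 1] - S[1, 2]^2 / S[2, 2]) / (df_t * S[2, 2]), 1e-300)
  tstat <- (S[1, 2] / S[2, 2]) / sqrt(scale2)
  pp <- pt(abs(tstat), df = df_t)
  cls <- if (pp > 0.95 && r_hat > 0) "positive"
  else if (pp > 0.95 && r_hat < 0) "negative" else "none"
  list(r = r_hat, pp = pp, classification = cls)
}

#' Correlation screen over all genes
#'
#' @param rates species x gene matrix (natural scale; log taken internally).
#' @param rmr_adj named adjusted RMR per species.
#' @param tree time tree.
#' @return data.frame per gene: `r`, `pp`, `classification`.
#' @export
correlation_screen <- function(rates, rmr_adj, tree) {
  genes <- colnames(rates)
  ln_rmr <- log(rmr_adj)
  out <- lapply(seq_along(genes), function(i) {
    res <- rate_trait_correlation(log(rates[, i]), ln_rmr, tree)
    data.frame(gene = genes[i], r = res$r, pp = res$pp,
               classification = res$classification, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
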