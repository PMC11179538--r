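// Core numerical kernels: transition-probability construction from a
// reversible-model eigendecomposition, Felsenstein pruning over an arbitrary
// state space (4 nucleotides or 61 sense codons), a mixture variant with
// per-edge rate-class assignment for branch-site models, and the
// Metropolis-within-Gibbs sampler for the Poisson-observation log-Brownian
// rate process.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// P(t) = D^-1/2 U exp(L t) U' D^1/2 supplied as V = D^-1/2 U, Vinv = U' D^1/2.
// [[Rcpp::export]]
arma::cube pmat_cube_cpp(const arma::mat& V, const arma::mat& Vinv,
                         const arma::vec& lambda, const arma::vec& tvec)
{
  const arma::uword S = V.n_rows, E = tvec.n_elem;
  arma::cube P(S, S, E);
  for (arma::uword e = 0; e < E; ++e) {
    P.slice(e) = V * arma::diagmat(arma::exp(lambda * tvec[e])) * Vinv;
    P.slice(e).clamp(0.0, 1.0); // numerical negatives / overshoot
  }
  return P;
}

static arma::vec pruning_impl(const arma::imat& edge, int ntip, int nnode,
                              const std::vector<const arma::cube*>& cubes,
                              const arma::ivec& which,
                              const arma::imat& tipstate,
                              const arma::vec& rootfreq)
{
  const arma::uword S = rootfreq.n_elem;
  const arma::uword npat = tipstate.n_cols;
  const int ntot = ntip + nnode;
  arma::cube part(S, npat, ntot, arma::fill::none);
  // tips: indicator partials (state 0 => missing, all ones)
  for (int i = 0; i < ntip; ++i) {
    arma::mat& sl = part.slice(i);
    sl.zeros();
    for (arma::uword j = 0; j < npat; ++j) {
      int st = tipstate(i, j);
      if (st <= 0) sl.col(j).ones(); else sl(st - 1, j) = 1.0;
    }
  }
  for (int i = ntip; i < ntot; ++i) part.slice(i).ones();

  arma::vec logscale(npat, arma::fill::zeros);
  const arma::uword E = edge.n_rows;
  for (arma::uword e = 0; e < E; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const arma::cube& P = *cubes[which[e]];
    part.slice(p) %= (P.slice(e) * part.slice(c));
    // guard against underflow on deep/saturated trees
    arma::rowvec m = arma::max(part.slice(p), 0);
    if (m.min() < 1e-140) {
      for (arma::uword j = 0; j < npat; ++j) {
        double mj = m[j];
        if (mj <= 0.0) continue; // impossible pattern; leave zeros
        part.slice(p).col(j) /= mj;
        logscale[j] += std::log(mj);
      }
    }
  }
  const int root = ntip; // ape convention: root id = ntip + 1
  arma::vec site = (rootfreq.t() * part.slice(root)).t();
  return arma::log(site) + logscale;
}

// Per-pattern log-likelihood, single substitution process on every edge.
// edge: postorder (parent, child), 1-based ape ids; P slices follow edge rows.
// [[Rcpp::export]]
arma::vec pruning_sitelik_cpp(const arma::imat& edge, int ntip, int nnode,
                              const arma::cube& P, const arma::imat& tipstate,
                              const arma::vec& rootfreq)
{
  std::vector<const arma::cube*> cubes(1, &P);
  arma::ivec which(edge.n_rows, arma::fill::zeros);
  return pruning_impl(edge, ntip, nnode, cubes, which, tipstate, rootfreq);
}

// Mixture-class variant: per edge pick P from one of three cubes
// (which[e] in {0,1,2}), as needed by branch-site site classes.
// [[Rcpp::export]]
arma::vec pruning_sitelik_mix_cpp(const arma::imat& edge, int ntip, int nnode,
                                  const arma::cube& P0, const arma::cube& P1,
                                  const arma::cube& P2, const arma::ivec& which,
                                  const arma::imat& tipstate,
                                  const arma::vec& rootfreq)
{
  std::vector<const arma::cube*> cubes(3);
  cubes[0] = &P0; cubes[1] = &P1; cubes[2] = &P2;
  return pruning_impl(edge, ntip, nnode, cubes, which, tipstate, rootfreq);
}

// ---------------------------------------------------------------------------
// Poisson-observation log-Brownian rate MCMC.
// Data: per edge e an integer substitution count y_e with exposure
// off_e = L * t_e; mean off_e * (r_parent + r_child)/2 (trapezoid).
// Latent: x_v = ln r_v at every node, BM along edges with variance v * t_e.
// Priors: x_root ~ N(mu0, s0^2); v = sigma^2_lnr ~ half-Cauchy(1).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List rate_mcmc_cpp(const arma::ivec& counts, const arma::vec& offs,
                   const arma::ivec& eparent, const arma::ivec& echild,
                   const arma::vec& te, int ntot, int root,
                   double mu0, double s0, int niter, int burn, int thin,
                   double x_init, double v_init)
{
  const int E = counts.n_elem;
  // incident edge lists per node
  std::vector< std::vector<int> > inc(ntot);
  for (int e = 0; e < E; ++e) {
    inc[eparent[e] - 1].push_back(e);
    inc[echild[e] - 1].push_back(e);
  }
  arma::vec x(ntot, arma::fill::value(x_init));
  double lv = std::log(v_init);

  arma::vec step(ntot, arma::fill::value(0.4));
  double step_v = 0.8;
  arma::vec acc(ntot, arma::fill::zeros), try_(ntot, arma::fill::zeros);
  double acc_v = 0, try_v = 0;

  auto edge_loglik = [&](int e, const arma::vec& xx) {
    double m = offs[e] * 0.5 * (std::exp(xx[eparent[e] - 1]) + std::exp(xx[echild[e] - 1]));
    if (m <= 0) m = 1e-300;
    return counts[e] * std::log(m) - m;
  };
  auto edge_prior = [&](int e, const arma::vec& xx, double v) {
    double d = xx[echild[e] - 1] - xx[eparent[e] - 1];
    return -0.5 * std::log(v * te[e]) - d * d / (2.0 * v * te[e]);
  };

  const int nkeep = (niter - burn) / thin;
  arma::mat out(nkeep, ntot + 1);
  int k = 0;

  for (int it = 0; it < niter; ++it) {
    double v = std::exp(lv);
    // node updates
    for (int nd = 0; nd < ntot; ++nd) {
      double cur = 0, prop = 0;
      arma::vec xp = x;
      xp[nd] = x[nd] + R::rnorm(0.0, step[nd]);
      for (int e : inc[nd]) {
        cur  += edge_loglik(e, x)  + edge_prior(e, x, v);
        prop += edge_loglik(e, xp) + edge_prior(e, xp, v);
      }
      if (nd == root - 1) {
        cur  += R::dnorm(x[nd],  mu0, s0, 1);
        prop += R::dnorm(xp[nd], mu0, s0, 1);
      }
      try_[nd] += 1;
      if (std::log(R::runif(0, 1)) < prop - cur) { x = xp; acc[nd] += 1; }
    }
    // variance update (log scale walk)
    {
      double lvp = lv + R::rnorm(0.0, step_v);
      double vp = std::exp(lvp);
      double cur = 0, prop = 0;
      for (int e = 0; e < E; ++e) {
        cur  += edge_prior(e, x, v);
        prop += edge_prior(e, x, vp);
      }
      // half-Cauchy(1) on v, plus log-Jacobian of v = exp(lv)
      cur  += -std::log1p(v * v)   + lv;
      prop += -std::log1p(vp * vp) + lvp;
      try_v += 1;
      if (std::log(R::runif(0, 1)) < prop - cur) { lv = lvp; acc_v += 1; }
    }
    // step-size adaptation during burn-in
    if (it < burn && (it + 1) % 100 == 0) {
      for (int nd = 0; nd < ntot; ++nd) {
        double r = acc[nd] / std::max(1.0, try_[nd]);
        step[nd] *= (r > 0.3) ? 1.25 : 0.8;
        acc[nd] = try_[nd] = 0;
      }
      double rv = acc_v / std::max(1.0, try_v);
      step_v *= (rv > 0.3) ? 1.25 : 0.8;
      acc_v = try_v = 0;
    }
    if (it >= burn && (it - burn) % thin == 0 && k < nkeep) {
      for (int nd = 0; nd < ntot; ++nd) out(k, nd) = x[nd];
      out(k, ntot) = std::exp(lv);
      ++k;
    }
  }
  return List::create(_["samples"] = out.rows(0, k - 1));
}
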