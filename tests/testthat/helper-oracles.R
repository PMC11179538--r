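# Independent oracles used across tests. These deliberately avoid the
# package's pruning/likelihood code paths: enumeration sums over internal
# states, dense matrix exponentials via series, and full 2^n sign
# enumeration for the signed-rank statistic.

# dense matrix exponential by scaling-and-squaring on the series (no eigen)
expm_series <- function(A) {
  n <- nrow(A)
  s <- max(0, ceiling(log2(max(1, max(abs(A))))))
  A <- A / 2^s
  X <- diag(n); term <- diag(n)
  for (k in 1:30) {
    term <- term %*% A / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# enumeration likelihood: sum over all internal-node state assignments
enum_loglik <- function(tree, tipstates, blens, Q, pi) {
  S <- length(pi)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e) expm_series(Q * blens[e]))
  npat <- ncol(tipstates)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), nint)))
  unname(sapply(seq_len(npat), function(j) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      state <- c(tipstates[, j], grid[g, ])
      pr <- unname(pi[state[ntip + 1L]])
      for (e in seq_len(nrow(tree$edge))) {
        child <- tree$edge[e, 2]
        if (child <= ntip && tipstates[child, j] == 0) next # missing tip
        pr <- pr * P[[e]][state[tree$edge[e, 1]], state[child]]
      }
      tot <- tot + pr
    }
    log(tot)
  }))
}

# full 2^n enumeration of the two-tailed signed-rank p
wilcoxon_brute <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m)
    sum(r[as.logical(bitwAnd(m, 2^(0:(n - 1))))]), numeric(1))
  min(1, 2 * min(mean(ws >= W - 1e-9), mean(ws <= W + 1e-9)))
}

random_time_tree <- function(n, depth = 100) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * (depth / max(ape::node.depth.edgelength(tr)))
  validate_time_tree(tr)
}

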