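#' Nucleotide and codon substitution models
#'
#' Both the simulators and the likelihood machinery share these builders.
#' Rate matrices are reversible and scaled to one expected substitution per
#' site (nucleotide models) or per codon (codon models) per unit branch
#' length at stationarity.
#'
#' @name models
NULL

NUC <- c("A", "C", "G", "T")

#' HKY (or JC) rate matrix
#' @param kappa transition/transversion rate ratio (1 for JC).
#' @param pi base frequencies in A,C,G,T order (uniform for JC).
#' @return list with `Q`, `pi`.
#' @export
hky_q <- function(kappa = 1, pi = rep(0.25, 4)) {
  stopifnot(kappa > 0, length(pi) == 4, all(pi > 0))
  pi <- pi / sum(pi)
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rate <- pi[j]
    if (any(transitions[, 1] == NUC[i] & transitions[, 2] == NUC[j]))
      rate <- rate * kappa
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  list(Q = Q, pi = pi)
}

# Eigendecomposition of a reversible generator via pi^(1/2) symmetrization.
# Returns V, Vinv, lambda with P(t) = V diag(exp(lambda t)) Vinv.
eig_reversible <- function(Q, pi) {
  d <- sqrt(pi)
  B <- Q * outer(d, 1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(V = e$vectors / d, Vinv = t(e$vectors * d), lambda = e$values)
}

# Transition matrices for all edges at once (S x S x nedge cube).
pmat_cube <- function(eig, tvec) {
  pmat_cube_cpp(eig$V, eig$Vinv, eig$lambda, as.numeric(tvec))
}

# ---- codon machinery ------------------------------------------------------

codon_universe <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    all64 <- apply(expand.grid(NUC, NUC, NUC, stringsAsFactors = FALSE)[, 3:1],
                   1L, paste0, collapse = "")
    gc <- Biostrings::GENETIC_CODE
    aa <- gc[all64]
    sense <- all64[aa != "*"]
    cache <<- list(codons = sense, aa = aa[aa != "*"],
                   stops = all64[aa == "*"])
    cache
  }
})

#' The 61 sense codons of the universal genetic code
#' @return character vector, alphabetical in A,C,G,T base order.
#' @export
sense_codons <- function() codon_universe()$codons

#' F3x4 codon frequencies
#'
#' Position-specific base frequencies multiplied across the three codon
#' positions, restricted to sense codons and renormalized.
#'
#' @param pos_freq 3 x 4 matrix of base frequencies (rows = codon positions,
#'   columns = A,C,G,T), or `NULL` for uniform.
#' @return named numeric vector over the 61 sense codons.
#' @export
f3x4_frequencies <- function(pos_freq = NULL) {
  cu <- codon_universe()
  if (is.null(pos_freq)) pos_freq <- matrix(0.25, 3, 4)
  stopifnot(nrow(pos_freq) == 3, ncol(pos_freq) == 4)
  pos_freq <- pos_freq / rowSums(pos_freq)
  colnames(pos_freq) <- NUC
  pi <- vapply(cu$codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    pos_freq[1, b[1]] * pos_freq[2, b[2]] * pos_freq[3, b[3]]
  }, numeric(1))
  pi / sum(pi)
}

# Precompute the single-nucleotide-change structure of the 61x61 generator:
# for each ordered pair, whether it is a 1-nt change, a transition, and
# whether it is nonsynonymous.
codon_change_structure <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cu <- codon_universe()
    n <- length(cu$codons)
    bases <- do.call(rbind, strsplit(cu$codons, ""))
    is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
    one <- matrix(FALSE, n, n); ts <- matrix(FALSE, n, n); ns <- matrix(FALSE, n, n)
    for (p in 1:3) {
      same_other <- matrix(TRUE, n, n)
      for (q in setdiff(1:3, p))
        same_other <- same_other & outer(bases[, q], bases[, q], "==")
      diff_p <- outer(bases[, p], bases[, p], "!=")
      hit <- same_other & diff_p
      one <- one | hit
      ts[hit] <- outer(bases[, p], bases[, p], is_ts)[hit]
    }
    ns <- outer(cu$aa, cu$aa, "!=")
    diag(one) <- FALSE
    cache <<- list(one = one, ts = ts, ns = ns)
    cache
  }
})

#' GY94-style codon rate matrix
#'
#' Single-nucleotide changes only; rate proportional to the target codon
#' frequency, multiplied by `kappa` for transitions and by `omega` for
#' nonsynonymous changes. Scaled to unit expected substitutions per codon at
#' stationarity.
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param pi codon frequencies over the 61 sense codons.
#' @param scale `"own"` normalizes to unit mean rate at stationarity for
#'   this omega; `"neutral"` normalizes by the omega = 1 matrix's mean rate
#'   instead, so site classes with omega > 1 genuinely evolve faster at the
#'   same branch length (the convention used by the branch-site mixture,
#'   where one branch length is shared across classes).
#' @return 61 x 61 generator matrix (rows sum to zero).
#' @export
build_codon_q <- function(kappa = 2, omega = 1, pi = f3x4_frequencies(),
                          scale = c("own", "neutral")) {
  scale <- match.arg(scale)
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61)
  st <- codon_change_structure()
  raw <- function(w) {
    Q <- matrix(0, 61, 61, dimnames = list(names(pi), names(pi)))
    Q[st$one] <- rep(pi, each = 61)[st$one]
    Q[st$one & st$ts] <- Q[st$one & st$ts] * kappa
    Q[st$one & st$ns] <- Q[st$one & st$ns] * w
    diag(Q) <- -rowSums(Q)
    Q
  }
  Q <- raw(omega)
  sc <- if (scale == "own") -sum(pi * diag(Q)) else -sum(pi * diag(raw(1)))
  if (sc > 0) Q <- Q / sc
  Q
}
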