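#' Fast-gene calling, trend detection and group comparisons
#'
#' A gene is fast-evolving in a focal species when its rate there
#' significantly exceeds its rates in the other species: exact two-tailed
#' Wilcoxon signed-rank on the paired differences, Benjamini-Hochberg FDR
#' across genes within the species, and a direction gate (median difference
#' positive). Trend genes show a strictly increasing posterior-median rate at
#' every node from the root down to the focal tip.
#'
#' @name rate_screen
NULL

#' Exact two-tailed Wilcoxon signed-rank p-value
#'
#' Exact under the full sign-assignment distribution, with average ranks for
#' tied absolute differences (the tied-rank distribution is enumerated
#' exactly by dynamic programming over doubled scores).
#'
#' @param diffs paired differences; zeros are dropped.
#' @return two-tailed p in (0, 1].
#' @export
exact_wilcoxon_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  if (!length(d)) {
    warning("all differences zero; p = 1")
    return(1)
  }
  n <- length(d)
  if (n > 25L) stop("exact enumeration supported for n <= 25")
  r2 <- as.integer(round(2 * rank(abs(d)))) # doubled to stay integral at ties
  w2 <- sum(r2[d > 0])
  total <- sum(r2)
  # distribution of the doubled positive-rank sum over 2^n sign patterns
  f <- numeric(total + 1L); f[1] <- 1
  for (s in r2) {
    g <- f
    g[(s + 1L):(total + 1L)] <- g[(s + 1L):(total + 1L)] + f[seq_len(total + 1L - s)]
    f <- g
  }
  f <- f / 2^n
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  p_le <- sum(f[seq_len(w2 + 1L)])
  min(1, 2 * min(p_ge, p_le))
}

#' Benjamini-Hochberg adjusted p-values
#' @param pvals vector of p-values in `[0, 1]`.
#' @return q-values (monotone step-up).
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' Call per-species fast-evolving genes
#'
#' @param rates species x gene matrix of per-species rates
#'   (subs/site/root-age).
#' @param focal focal species (row name).
#' @param alpha FDR threshold.
#' @return data.frame per gene: `gene`, `p`, `q`, `median_d`, `fast`. Genes
#'   with missing species are skipped (attribute `skipped`).
#' @export
call_fast_genes <- function(rates, focal, alpha = 0.05) {
  stopifnot(nrow(rates) >= 3, focal %in% rownames(rates))
  ok <- colSums(is.na(rates)) == 0L
  skipped <- colnames(rates)[!ok]
  if (length(skipped)) message(length(skipped), " gene(s) skipped (missing species)")
  r <- rates[, ok, drop = FALSE]
  other <- setdiff(rownames(r), focal)
  p <- numeric(ncol(r)); md <- numeric(ncol(r))
  for (j in seq_len(ncol(r))) {
    d <- r[focal, j] - r[other, j]
    p[j] <- exact_wilcoxon_signed_rank(d)
    md[j] <- median(d)
  }
  q <- bh_adjust(p)
  out <- data.frame(gene = colnames(r), p = p, q = q, median_d = md,
                    fast = (q < alpha) & (md > 0), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Detect constant-trend genes along the root-to-focal path
#'
#' @param node_rates node x gene matrix of posterior-median instant rates
#'   (rows indexed by ape node id), or a single `rate_process_fit`.
#' @param tree time tree.
#' @param focal focal tip label.
#' @param strict require strict increase at every step (default); otherwise
#'   allow equal consecutive values.
#' @return data.frame per gene: `gene`, `trend` (flag), `fold`
#'   (tip rate / root rate), `n_steps`.
#' @export
detect_trend_genes <- function(node_rates, tree, focal, strict = TRUE) {
  if (inherits(node_rates, "rate_process_fit"))
    node_rates <- matrix(node_rates$rate, ncol = 1,
                         dimnames = list(NULL, "gene"))
  path_e <- root_to_tip_edges(tree)[[focal]]
  nodes <- c(tree$edge[path_e[1], 1], tree$edge[path_e, 2])
  cmp <- if (strict) `>` else `>=`
  res <- apply(node_rates[nodes, , drop = FALSE], 2L, function(r) {
    c(trend = all(cmp(r[-1], r[-length(r)])), fold = r[length(r)] / r[1])
  })
  data.frame(gene = colnames(node_rates), trend = as.logical(res["trend", ]),
             fold = res["fold", ], n_steps = length(nodes) - 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA, Tukey HSD and optional ANCOVA on grouped rates
#'
#' @param rates species x gene matrix; observations are the per-gene rates,
#'   groups are the species.
#' @param ancova optional data.frame with columns `response`, `group`,
#'   `covariate` (one row per group-level unit) for an
#'   `response ~ group + covariate` F-test.
#' @return list: `anova` (F, p), `tukey` (data.frame of pairwise adjusted p),
#'   `ancova` (F, p for the group term, or NULL).
#' @export
group_comparisons <- function(rates, ancova = NULL) {
  df <- data.frame(value = as.vector(t(rates)),
                   group = factor(rep(rownames(rates), each = ncol(rates))))
  if (all(vapply(split(df$value, df$group), var, numeric(1)) == 0))
    stop("zero within-group variance everywhere: F undefined")
  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  anc <- NULL
  if (!is.null(ancova)) {
    m <- lm(response ~ group + covariate, data = ancova)
    a <- anova(m)
    anc <- list(F = a["group", "F value"], p = a["group", "Pr(>F)"])
  }
  list(anova = list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1]),
       tukey = tukey, ancova = anc)
}
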