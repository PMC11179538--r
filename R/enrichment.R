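#' Gene-set over-representation against the single-copy-ortholog background
#'
#' Upper-tail hypergeometric test per annotation term, Benjamini-Hochberg
#' FDR across the terms tested. Terms annotated to fewer than two background
#' genes are untestable and skipped; annotations are tested as given (no
#' parent-term propagation).
#'
#' @param subset character vector of genes of interest (must lie in the
#'   background).
#' @param annotations data.frame with columns `gene`, `term`.
#' @param background character vector of all genes (the test universe).
#' @param min_term_genes smallest background annotation count for a term to
#'   be testable.
#' @return data.frame per term: `term`, `k` (subset hits), `n` (subset
#'   size), `K` (background hits), `N` (background size), `p`, `q`,
#'   `enrichment` (`(k/n)/(K/N)`), sorted by `q`.
#' @export
hypergeom_enrich <- function(subset, annotations, background,
                             min_term_genes = 2L) {
  if (!length(subset)) {
    warning("empty gene subset")
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), enrichment = numeric(0)))
  }
  stopifnot(all(subset %in% background))
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term")])
  Kt <- table(ann$term)
  terms <- names(Kt)[Kt >= min_term_genes]
  N <- length(unique(background))
  n <- length(unique(subset))
  out <- lapply(terms, function(tm) {
    genes_tm <- ann$gene[ann$term == tm]
    K <- length(genes_tm)
    k <- length(intersect(genes_tm, subset))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               enrichment = (k / n) / (K / N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- bh_adjust(out$p)
  out[order(out$q, out$p), c("term", "k", "n", "K", "N", "p", "q", "enrichment")]
}
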