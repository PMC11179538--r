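#' Tree input, validation and geometry primitives
#'
#' Trees are handled as `ape::phylo` objects throughout. A *time tree* is a
#' rooted ultrametric phylogeny whose edge lengths are durations in million
#' years (My); every root-to-tip path sums to the root age. All downstream
#' covariance models (Brownian, Ornstein-Uhlenbeck, PGLS) consume only path
#' times, so polytomies are permitted.
#'
#' @name phylo_io
NULL

#' Parse a newick string into a validated tree
#'
#' Accepts quoted labels and square-bracket comments, requires a terminating
#' semicolon. In `"time"` mode the tree must be rooted and ultrametric (all
#' root-to-tip depths equal within relative tolerance `tol`); in `"subst"`
#' mode branch lengths are interpreted as substitutions/site and only
#' non-negativity is enforced.
#'
#' @param text newick string.
#' @param mode `"time"` or `"subst"`.
#' @param tol relative tolerance for the ultrametricity check.
#' @return an `ape::phylo`; time trees carry attribute `root_age` (My).
#' @export
parse_newick <- function(text, mode = c("time", "subst"), tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1L)
  # cheap structural scan so malformed input fails with a character offset
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  in_quote <- FALSE; in_comment <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_comment) { if (ch == "]") in_comment <- FALSE; next }
    if (ch == "'") { in_quote <- !in_quote; next }
    if (in_quote) next
    if (ch == "[") { in_comment <- TRUE; next }
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("newick parse error at character ", i,
                           ": unbalanced ')'")
    }
  }
  if (depth != 0L) stop("newick parse error at character ", length(chars),
                        ": ", depth, " unclosed '('")
  if (!grepl(";", text, fixed = TRUE))
    stop("newick parse error at character ", nchar(text),
         ": missing ';' terminator")
  clean <- gsub("\\[[^]]*\\]", "", text)
  tr <- tryCatch(ape::read.tree(text = clean),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unreadable tree")
  tr$tip.label <- gsub("^'|'$", "", tr$tip.label)
  if (is.null(tr$edge.length)) stop("newick parse error: no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length in input")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (mode == "subst") return(tr)
  validate_time_tree(tr, tol = tol)
}

#' Validate a phylo object as an ultrametric time tree
#' @param tree `ape::phylo`.
#' @param tol relative ultrametricity tolerance.
#' @return the tree with attribute `root_age` set.
#' @export
validate_time_tree <- function(tree, tol = 1e-6) {
  # a basal polytomy is acceptable; only a structurally root-less edge list
  # is not (every phylo edge table has exactly one parentless node)
  root_cand <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(root_cand) != 1L) stop("time tree must have exactly one root")
  dep <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  T_root <- max(dep)
  worst <- which.max(abs(dep - T_root))
  if (T_root <= 0) stop("tree has zero depth")
  if (max(abs(dep - T_root)) / T_root > tol)
    stop("tree is not ultrametric: tip '", tree$tip.label[worst],
         "' has depth ", format(dep[worst]), " vs root age ", format(T_root))
  attr(tree, "root_age") <- T_root
  tree
}

#' Root age of a time tree (My)
#' @param tree validated time tree.
#' @export
root_age <- function(tree) {
  ra <- attr(tree, "root_age")
  if (is.null(ra)) ra <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  ra
}

#' Node ages of a time tree (tips at 0, root at the root age)
#' @param tree validated time tree.
#' @return numeric vector over node ids `1..(Ntip+Nnode)`.
#' @export
node_ages <- function(tree) {
  root_age(tree) - ape::node.depth.edgelength(tree)
}

#' Write a tree to newick
#' @param tree `ape::phylo`.
#' @param file optional path; when `NULL` the string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Midpoint-root an unrooted tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path, so the two
#' farthest tips are equidistant from the root.
#'
#' @param tree `ape::phylo` with branch lengths in substitutions/site.
#' @return rooted `ape::phylo`.
#' @export
midpoint_root <- function(tree) {
  if (ape::Ntip(tree) < 3L) stop("midpoint rooting needs at least 3 tips")
  if (all(tree$edge.length == 0)) stop("all branch lengths zero: midpoint undefined")
  phytools::midpoint.root(tree)
}

#' Shared root-to-MRCA path-time matrix
#'
#' For every pair of tips, the time (My) shared from the root down to their
#' most recent common ancestor; the diagonal is the root age. This is the
#' Gram matrix of root-to-tip paths and the Brownian-motion covariance
#' structure used by every comparative model in the package.
#'
#' @param tree validated time tree.
#' @return symmetric matrix with tip labels as dimnames.
#' @export
shared_path_matrix <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Root-to-tip edge paths
#'
#' @param tree rooted `ape::phylo`.
#' @return list per tip label: integer vector of edge row indices
#'   (in `tree$edge`) from the root down to that tip.
#' @export
root_to_tip_edges <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent_edge <- integer(ntip + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  out <- lapply(seq_len(ntip), function(tip) {
    path <- integer(0)
    nd <- tip
    while (nd != root) {
      e <- parent_edge[nd]
      path <- c(e, path)
      nd <- tree$edge[e, 1]
    }
    path
  })
  names(out) <- tree$tip.label
  out
}

#' Read a FASTA alignment into the package's matrix form
#' @param file FASTA path.
#' @param codon_aware flag alignment columns as codon-structured.
#' @return character matrix (taxa x sites, uppercase) with attribute
#'   `codon_aware`.
#' @export
read_alignment <- function(file, codon_aware = FALSE) {
  dn <- ape::read.FASTA(file)
  m <- toupper(as.character(as.matrix(dn)))
  as_alignment(m, codon_aware = codon_aware)
}

#' Construct/validate the alignment container
#' @param m character matrix, rows = taxa (rownames are labels), columns =
#'   sites; letters in `A,C,G,T,-,N`.
#' @param codon_aware when `TRUE` the number of columns must divide by 3.
#' @export
as_alignment <- function(m, codon_aware = FALSE) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate sequence labels")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) stop("unexpected alignment characters: ",
                        paste(bad, collapse = ","))
  if (codon_aware && ncol(m) %% 3L != 0L)
    stop("codon-aware alignment length not divisible by 3")
  attr(m, "codon_aware") <- codon_aware
  m
}

#' Write an alignment to FASTA
#' @param aln alignment matrix from [as_alignment()].
#' @param file output path.
#' @export
write_alignment <- function(aln, file) {
  seqs <- apply(aln, 1L, paste0, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), file)
  invisible(file)
}
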