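test_that("newick parsing validates, round-trips and reports offsets", {
  tr <- parse_newick("((A:1,B:1):1,C:2);", mode = "time")
  expect_equal(root_age(tr), 2)
  expect_equal(tr$Nnode, 2L)
  # round trip preserves topology and lengths
  tr2 <- parse_newick(write_newick(tr), mode = "time")
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(tr2)), 0)
  expect_equal(sort(tr$edge.length), sort(tr2$edge.length), tolerance = 1e-9)
  # non-ultrametric input in time mode names the offending tip
  expect_error(parse_newick("((A:1,B:2):1,C:2);", mode = "time"),
               "not ultrametric: tip")
  # malformed strings carry a character offset
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "parse error")
  expect_error(parse_newick("((A:1,B:1):1,C:2)"), "character")
  # subst mode accepts non-ultrametric trees
  expect_silent(parse_newick("((A:1,B:2):1,C:2);", mode = "subst"))
  # quoted labels and comments
  tq <- parse_newick("(('sp one':1,B:1):1,C:2)[a comment];", mode = "time")
  expect_true("sp one" %in% tq$tip.label)
})

test_that("round trip is the identity on random trees", {
  set.seed(42)
  for (i in 1:20) {
    tr <- random_time_tree(sample(4:12, 1))
    tr2 <- parse_newick(write_newick(tr), mode = "time")
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(tr2)), 0)
    m1 <- shared_path_matrix(tr); m2 <- shared_path_matrix(tr2)
    expect_equal(m1[rownames(m2), colnames(m2)], m2, tolerance = 1e-9)
  }
})

test_that("midpoint rooting places the root at the longest-path midpoint", {
  # star: longest path A-B of length 4, midpoint 2 from each
  mr <- midpoint_root(ape::read.tree(text = "(A:1,B:3,C:1);"))
  d <- ape::node.depth.edgelength(mr)[seq_len(3)]
  names(d) <- mr$tip.label
  expect_equal(unname(d[c("A", "B")]), c(2, 2), tolerance = 1e-9)
  # chain A - B with C hanging off B's end: midpoint inside C's branch
  # (A..C = 2 + 5 = 7, so both farthest tips sit 3.5 from the root)
  mr2 <- midpoint_root(ape::read.tree(text = "(A:2,B:0,C:5);"))
  d2 <- ape::node.depth.edgelength(mr2)[seq_len(3)]
  names(d2) <- mr2$tip.label
  expect_equal(unname(d2[c("A", "C")]), c(3.5, 3.5), tolerance = 1e-9)
  expect_equal(max(d2), 3.5, tolerance = 1e-9)
  # idempotence: re-rooting an already midpoint-rooted tree changes nothing
  mr3 <- midpoint_root(mr2)
  d3 <- ape::node.depth.edgelength(mr3)[seq_len(3)]
  names(d3) <- mr3$tip.label
  expect_equal(d3[names(d2)], d2, tolerance = 1e-9)
  expect_error(midpoint_root(ape::read.tree(text = "(A:0,B:0,C:0);")),
               "midpoint undefined")
})

test_that("shared path matrix reads node ages and is PSD", {
  tr <- parse_newick("((A:1,B:1):1,C:2);", mode = "time")
  C <- shared_path_matrix(tr)
  expect_equal(diag(C), c(A = 2, B = 2, C = 2))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  # star tree: off-diagonals all zero
  st <- parse_newick("(A:3,B:3,C:3,D:3);", mode = "time")
  Cs <- shared_path_matrix(st)
  expect_true(all(Cs[upper.tri(Cs)] == 0))
  # PSD over random trees (Gram matrix of shared paths)
  set.seed(7)
  for (i in 1:100) {
    Ci <- shared_path_matrix(random_time_tree(sample(4:10, 1)))
    expect_gte(min(eigen(Ci, symmetric = TRUE, only.values = TRUE)$values),
               -1e-9)
  }
})

test_that("polytomies pass validation and geometry", {
  tr <- parse_newick("((A:1,B:1,C:1):1,D:2);", mode = "time")
  C <- shared_path_matrix(tr)
  expect_equal(C["A", "C"], 1)
  expect_equal(root_age(tr), 2)
})

test_that("alignment container validates labels and codon structure", {
  m <- matrix(c("A", "C", "G", "T", "A", "C"), 2, 3,
              dimnames = list(c("a", "b"), NULL))
  expect_silent(as_alignment(m, codon_aware = TRUE))
  expect_error(as_alignment(m[, 1:2, drop = FALSE], codon_aware = TRUE),
               "divisible by 3")
  bad <- m; bad[1, 1] <- "X"
  expect_error(as_alignment(bad), "unexpected")
  # FASTA round trip
  f <- tempfile(fileext = ".fa")
  write_alignment(as_alignment(m), f)
  expect_equal(read_alignment(f), m, ignore_attr = TRUE)
})
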