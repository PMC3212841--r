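test_that("harvest emits n-3 columns per fully resolved, fully supported tree", {
  for (n in c(5, 9, 14)) {
    tr <- rtree_sup(n, n)
    m <- harvest_bipartitions(list(tr), 0.95)
    expect_equal(ncol(m$mat), n - 3)
    expect_true(all(m$mat %in% c("0", "1")))
  }
})

test_that("the support threshold is inclusive and sub-threshold edges are dropped", {
  tr <- ape::read.tree(text = "((A,B)0.94,((C,D)0.95,E)1.0,F);")
  m <- harvest_bipartitions(list(tr), 0.95)
  expect_equal(ncol(m$mat), 2)          # 0.94 excluded; 0.95 and 1.0 kept
  expect_setequal(m$support, c(0.95, 1.0))
})

test_that("duplicate bipartitions from different trees are retained as characters", {
  tr <- rtree_sup(6, 7)
  m <- harvest_bipartitions(list(tr, tr), 1.0)
  expect_equal(ncol(m$mat), 2 * (6 - 3))
})

test_that("taxa absent from a family are coded missing", {
  t1 <- rtree_sup(6, 1)
  t2 <- rtree_sup(5, 2)                 # t01..t05: lacks t06
  m <- harvest_bipartitions(list(t1, t2))
  cols2 <- which(m$family == 2)
  expect_true(all(m$mat["t06", cols2] == "?"))
  expect_true(all(m$mat["t06", m$family == 1] %in% c("0", "1")))
})

test_that("an empty tree list is an error", {
  expect_error(harvest_bipartitions(list()), "empty")
})

test_that("the supertree recovers a single source tree (compatible characters)", {
  tr <- rtree_sup(8, 99)
  m <- harvest_bipartitions(list(tr))
  sup <- build_mrp_supertree(m, seed = 4)
  expect_identical(tkey(sup), tkey(tr))
  expect_equal(attr(sup, "pscore"), ncol(m$mat))  # each column fits perfectly
})

test_that("majority signal wins: exhaustive parsimony oracle on 5 taxa", {
  tT <- ape::read.tree(text = "((a,b),(c,d),e);")
  tA <- ape::read.tree(text = "((a,c),(b,d),e);")
  tT$node.label <- rep("1", tT$Nnode)
  tA$node.label <- rep("1", tA$Nnode)
  m <- harvest_bipartitions(list(tT, tT, tA))
  sup <- build_mrp_supertree(m, seed = 1)
  # oracle: score every 5-leaf topology against the matrix
  dat <- lgtnet:::mrp_phyDat(m)
  all5 <- phangorn::allTrees(5, rooted = FALSE, tip.label = letters[1:5])
  scores <- vapply(all5, phangorn::parsimony, numeric(1), data = dat)
  best <- vapply(all5[scores == min(scores)], tkey, character(1))
  expect_length(best, 1)
  expect_identical(tkey(sup), best)
  expect_identical(tkey(sup), tkey(tT))
})

test_that("conflicting matrices give seed-independent parsimony scores", {
  trees <- lapply(1:6, function(s) rtree_sup(9, 100 + s))
  m <- harvest_bipartitions(trees)
  s1 <- build_mrp_supertree(m, seed = 1)
  s2 <- build_mrp_supertree(m, seed = 2)
  expect_equal(attr(s1, "pscore"), attr(s2, "pscore"))
})

test_that("an all-missing taxon is reported by name", {
  t1 <- rtree_sup(6, 1)
  t2 <- rtree_sup(5, 2)
  m <- harvest_bipartitions(list(t1, t2))
  m$mat["t06", ] <- "?"
  expect_error(build_mrp_supertree(m), "t06")
})

test_that("the supertree displays every column of a compatible matrix", {
  tr <- rtree_sup(12, 5)
  m <- harvest_bipartitions(list(tr, restrict_tree2(tr, tr$tip.label[1:8])))
  sup <- build_mrp_supertree(m, seed = 1)
  ref_masks <- tree_splits(sup)$mask
  # every harvested split, restricted to its family, must be displayed
  expect_identical(tkey(sup), tkey(tr))
})

test_that("the MRP matrix exports as relaxed PHYLIP", {
  tr <- rtree_sup(5, 3)
  m <- harvest_bipartitions(list(tr))
  tf <- withr::local_tempfile()
  write_mrp_phylip(m, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], paste(5, 2))
  expect_length(lines, 6)
})
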