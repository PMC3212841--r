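# Frozen expected values below were computed with the pendant-subtree
# agreement oracle (helper-oracles.R) over the complete tree space.

test_that("identical topologies have distance zero", {
  tr <- rtree_sup(9, 5)
  res <- spr_edit_distance(tr, tr)
  expect_equal(res$distance, 0L)
  expect_true(res$resolved)
})

test_that("exchanging two leaves across cherries costs two moves", {
  a <- ape::read.tree(text = "((A,B),(C,D),E);")
  b <- ape::read.tree(text = "((A,C),(B,D),E);")
  expect_equal(spr_edit_distance(a, b)$distance, 2L)   # oracle value
})

test_that("a caterpillar and its leaf-order reversal are the same topology", {
  cat7 <- ape::unroot(ape::read.tree(text = "(a,(b,(c,(d,(e,(f,g))))));"))
  rev7 <- ape::unroot(ape::read.tree(text = "(g,(f,(e,(d,(c,(b,a))))));"))
  expect_identical(tkey(cat7), tkey(rev7))
  expect_equal(spr_edit_distance(cat7, rev7)$distance, 0L)
})

test_that("a 7-leaf caterpillar against a balanced tree matches the oracle", {
  cat7 <- ape::unroot(ape::read.tree(text = "(a,(b,(c,(d,(e,(f,g))))));"))
  bal7 <- ape::unroot(ape::read.tree(text = "(((a,e),(b,f)),(c,g),d);"))
  d <- spr_edit_distance(cat7, bal7)$distance
  o <- oracle_spr_graph(7)
  expect_equal(d, o$dist[match(tkey(cat7), o$keys), match(tkey(bal7), o$keys)])
  expect_equal(d, 3L)                                  # frozen oracle value
})

test_that("k random moves give distance between 1 and k, symmetric", {
  for (r in 1:6) {
    tr <- rtree_sup(sample(7:14, 1), 300 + r)
    k <- sample(1:3, 1)
    moved <- random_spr_moves(tr, k)
    d1 <- spr_edit_distance(moved, tr)$distance
    d2 <- spr_edit_distance(tr, moved)$distance
    expect_gte(d1, 1L)
    expect_lte(d1, k)
    expect_equal(d1, d2)
  }
})

test_that("the search reports UNRESOLVED beyond its budget", {
  a <- ape::read.tree(text = "((A,B),(C,D),E);")
  b <- ape::read.tree(text = "((A,C),(B,D),E);")
  res <- spr_edit_distance(a, b, d_max = 1)
  expect_true(is.na(res$distance))
  expect_false(res$resolved)
  expect_equal(res$budget, 1L)
})

test_that("a collapsed multifurcating test tree uses the displays goal", {
  ref <- rtree_sup(8, 17)
  tst <- restrict_tree2(ref, ref$tip.label)
  sp <- tree_splits(tst)
  # weaken two edges, strengthen the rest: collapse leaves a polytomy
  sup <- rep(1, nrow(sp)); sup[1:2] <- 0.5
  tst <- tree_from_splits(tst$tip.label, sp$mask, sup)
  col <- collapse_low_support(tst, 0.95)
  expect_lt(col$Nnode, length(col$tip.label) - 2)
  res <- spr_edit_distance(col, ref)
  expect_equal(res$distance, 0L)                 # compatible: displayed
  # now conflict on a resolved edge: distance >= 1 through the same goal
  moved <- random_spr_moves(restrict_tree2(ref, ref$tip.label), 1)
  spm <- tree_splits(moved)
  half <- tree_from_splits(moved$tip.label, spm$mask,
                           c(0.5, rep(1, nrow(spm) - 1)))
  halfcol <- collapse_low_support(half, 0.95)
  if (is_discordant(half, ref)) {
    res2 <- spr_edit_distance(halfcol, ref)
    expect_gte(res2$distance, 1L)
  }
})

test_that("pruning to shared taxa happens before the search", {
  ref <- rtree_sup(12, 23)
  tst <- restrict_tree2(ref, ref$tip.label[1:8])
  tst2 <- random_spr_moves(tst, 1)
  expect_equal(spr_edit_distance(tst2, ref)$distance, 1L)
})
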