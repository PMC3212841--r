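# Support-aware discordance against the reference tree, and the exact SPR
# edit distance used to count the implied transfer events.

restrict_tree <- function(tree, labels) {
  drop <- setdiff(tree$tip.label, labels)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  if (ape::is.rooted(tree) && tree$Nnode > 1) tree <- ape::unroot(tree)
  tree
}

#' Is a test tree discordant with the reference?
#'
#' The reference is pruned to the test taxon set, the test tree is collapsed
#' at the support threshold, and the trees are compared as unrooted split
#' sets.  The test is discordant iff at least one *resolved* test split is
#' incompatible with a split of the restricted reference: polytomies left by
#' the collapse are treated as uncertainty, not conflict.
#'
#' @param test `phylo` with supports as node labels; leaves must be a subset
#'   of the reference leaves.
#' @param reference `phylo` (typically the MRP supertree).
#' @param threshold support collapse threshold (inclusive), default 0.95.
#' @return logical.
#' @export
is_discordant <- function(test, reference, threshold = 0.95) {
  shared <- intersect(test$tip.label, reference$tip.label)
  if (length(shared) < 4)
    stop("fewer than 4 shared taxa: no meaningful comparison")
  if (!all(test$tip.label %in% reference$tip.label))
    stop("test leaves must be a subset of the reference leaves")
  ref <- restrict_tree(reference, shared)
  tst <- collapse_low_support(restrict_tree(test, shared), threshold)
  full <- bitwShiftL(1L, length(shared)) - 1L
  tsp <- tree_splits(tst)$mask
  rsp <- tree_splits(ref)$mask
  for (m in tsp) {
    if (m %in% rsp) next
    for (r in rsp)
      if (!splits_compatible(m, r, full)) return(TRUE)
  }
  FALSE
}

# Distance-preserving reduction: repeatedly collapse cherries (two leaves on
# a common degree-3 node) present in both trees to a single leaf.  Nested
# identical pendant subtrees reduce by iteration.
find_cherries <- function(tree) {
  e <- tree$edge
  ntip <- length(tree$tip.label)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  out <- list()
  for (nd in names(adj)) {
    v <- as.integer(nd)
    nbs <- adj[[nd]]
    if (v <= ntip || length(nbs) != 3) next
    tips <- nbs[nbs <= ntip]
    if (length(tips) >= 2) {
      cmb <- utils::combn(sort(tree$tip.label[tips]), 2)
      for (k in seq_len(ncol(cmb))) out[[length(out) + 1]] <- cmb[, k]
    }
  }
  out
}

reduce_tree_pair <- function(t1, t2) {
  repeat {
    if (length(t1$tip.label) <= 4) break
    c1 <- vapply(find_cherries(t1), paste, character(1), collapse = "\r")
    c2 <- vapply(find_cherries(t2), paste, character(1), collapse = "\r")
    common <- intersect(c1, c2)
    if (!length(common)) break
    pair <- strsplit(sort(common)[1], "\r", fixed = TRUE)[[1]]
    t1 <- ape::drop.tip(t1, pair[2])
    t2 <- ape::drop.tip(t2, pair[2])
  }
  list(t1, t2)
}

#' Exact SPR edit distance between unrooted trees
#'
#' Returns the minimum number of subtree prune-and-regraft operations
#' separating the two topologies, the phylogenetic proxy for the number of
#' transfer events implied by the discordance.  Both trees are restricted to
#' their shared taxa; common pendant subtrees are then collapsed (a
#' distance-preserving reduction) and the remaining core is searched by
#' breadth-first expansion of SPR neighbourhoods with canonical split-set
#' hashing - bidirectional when both trees are binary.  If the test tree
#' carries polytomies (after a support collapse) the distance returned is
#' the minimum over all resolutions: the search runs from the binary
#' reference and stops at the first tree displaying every resolved test
#' split.
#'
#' The search is exact whenever it returns a distance.  `d_max` and
#' `max_nodes` bound the search; beyond either bound the result is
#' `UNRESOLVED` (`NA` distance, `resolved = FALSE`).
#'
#' @param test,reference `phylo` objects (test already support-collapsed if
#'   that is intended; see [collapse_low_support()]).
#' @param d_max maximum distance searched (default 6).
#' @param max_nodes cap on distinct topologies visited (default 1e6).
#' @return list with `distance` (integer or `NA`), `resolved` (logical),
#'   `nodes` (topologies visited), `budget` (= `d_max`).
#' @export
spr_edit_distance <- function(test, reference, d_max = 6L, max_nodes = 1e6) {
  stopifnot(d_max >= 1)
  shared <- intersect(test$tip.label, reference$tip.label)
  if (length(shared) < 4)
    stop("fewer than 4 shared taxa: no meaningful comparison")
  ref <- restrict_tree(reference, shared)
  tst <- restrict_tree(test, shared)
  if (!is_binary_unrooted(ref))
    stop("reference tree must be fully resolved")
  full <- bitwShiftL(1L, length(shared)) - 1L
  tsp <- tree_splits(tst)$mask
  rsp <- tree_splits(ref)$mask
  if (all(tsp %in% rsp))
    return(list(distance = 0L, resolved = TRUE, nodes = 0,
                budget = as.integer(d_max)))
  binary_test <- is_binary_unrooted(tst)
  if (binary_test) {
    red <- reduce_tree_pair(tst, ref)
    tst <- red[[1]]; ref <- red[[2]]
  }
  labels <- sort(ref$tip.label)
  e_ref <- std_edge(ref, labels)
  if (binary_test) {
    e_tst <- std_edge(tst, labels)
    res <- cpp_spr_distance(e_tst, e_ref, length(labels),
                            as.integer(d_max), max_nodes, FALSE, numeric(0))
  } else {
    goal <- tree_splits(tst)$mask
    res <- cpp_spr_distance(e_ref, e_ref, length(labels),
                            as.integer(d_max), max_nodes, TRUE,
                            as.numeric(goal))
  }
  list(distance = if (res$resolved) as.integer(res$distance) else NA_integer_,
       resolved = res$resolved, nodes = res$nodes,
       budget = as.integer(d_max))
}

is_binary_unrooted <- function(tree) {
  n <- length(tree$tip.label)
  tree$Nnode == n - 2L
}

#' All SPR neighbours of a binary unrooted tree, as topology keys
#'
#' Exposes the neighbourhood generator behind [spr_edit_distance()]; used to
#' assemble complete SPR graphs for small leaf counts.
#' @param tree binary unrooted `phylo`.
#' @return character vector of topology keys (comma-joined sorted split
#'   masks over the sorted taxon set), deduplicated.
#' @export
spr_neighbor_keys <- function(tree) {
  if (!is_binary_unrooted(tree)) stop("tree must be binary and unrooted")
  cpp_spr_neighbor_keys(std_edge(tree), length(tree$tip.label))
}

#' Apply random SPR moves to a tree
#'
#' Each move is drawn via [phangorn::rSPR()] and rejected (and redrawn) if
#' it reproduces the topology it started from, so `k` moves plant an edit
#' distance of at least 1 and at most `k`.
#' @param tree binary unrooted `phylo`.
#' @param moves number of moves.
#' @return a `phylo`.
#' @export
random_spr_moves <- function(tree, moves) {
  for (i in seq_len(moves)) {
    key <- topology_key(tree)
    repeat {
      cand <- phangorn::rSPR(tree, moves = 1)
      cand <- ape::unroot(cand)
      if (topology_key(cand) != key) break
    }
    tree <- cand
  }
  tree
}
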