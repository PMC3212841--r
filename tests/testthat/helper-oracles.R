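# Independent oracles used across the suite.
#
# SPR oracle: the complete SPR graph on all unrooted binary topologies for
# a small leaf count, with adjacency derived from the pendant-subtree
# agreement characterisation of "distance <= 1" (two trees are one SPR
# apart iff some edge-side Y is pendant in both with the identical rooted
# subtree - keyed over Y plus a fixed representative leaf of the
# complement - and identical complement restriction).  This never touches
# the package's SPR neighbourhood generator or search.

tkey <- function(tr) paste(tree_splits(tr)$mask, collapse = ",")

popc <- function(m) vapply(m, function(x)
  sum(bitwAnd(bitwShiftR(as.integer(x), 0:30), 1L)), numeric(1))

induced_key <- function(masks, subset_mask) {
  sub <- bitwAnd(c(masks, 0L), subset_mask)
  k <- popc(subset_mask)
  low <- bitwAnd(subset_mask, -subset_mask)
  sub <- ifelse(bitwAnd(sub, low) != 0L,
                bitwAnd(subset_mask, bitwNot(sub)), sub)
  pc <- popc(sub)
  sub <- unique(sub[pc >= 2 & pc <= k - 2])
  paste(sort(sub), collapse = ",")
}

oracle_spr_graph <- function(n) {
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = letters[1:n])
  keys <- vapply(trees, tkey, character(1))
  full <- bitwShiftL(1L, n) - 1L
  entries <- new.env(parent = emptyenv())
  for (i in seq_along(trees)) {
    masks <- tree_splits(trees[[i]])$mask
    sides <- unique(c(masks, bitwAnd(full, bitwNot(masks)),
                      bitwShiftL(1L, 0:(n - 1))))
    sides <- sides[popc(sides) <= n - 2]
    for (Y in sides) {
      X <- bitwAnd(full, bitwNot(Y))
      z <- bitwAnd(X, -X)
      e <- paste(Y, induced_key(masks, X),
                 induced_key(masks, bitwOr(Y, z)), sep = "|")
      entries[[e]] <- c(entries[[e]], i)
    }
  }
  el <- list()
  for (e in ls(entries)) {
    v <- unique(entries[[e]])
    if (length(v) >= 2) el[[length(el) + 1]] <- t(utils::combn(v, 2))
  }
  el <- unique(do.call(rbind, el))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  g <- igraph::add_vertices(g, max(0, length(trees) - igraph::vcount(g)))
  list(trees = trees, keys = keys, dist = igraph::distances(g))
}

# all-pairs distances through the package's own neighbourhood generator
impl_spr_graph_dist <- function(trees, keys) {
  idx <- stats::setNames(seq_along(keys), keys)
  el <- do.call(rbind, lapply(seq_along(trees), function(i)
    cbind(i, idx[spr_neighbor_keys(trees[[i]])])))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  igraph::distances(g)
}

# exact two-sided Fisher p by direct hypergeometric enumeration
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(xs, r1, n - r1, c1)
  sum(pr[pr <= stats::dhyper(a, r1, n - r1, c1) * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating all group assignments
enum_ranksum_p <- function(a, b) {
  v <- c(a, b); n1 <- length(a); n <- length(v)
  rk <- rank(v)
  combs <- utils::combn(n, n1)
  W <- colSums(matrix(rk[combs], nrow = n1))
  EW <- n1 * (n + 1) / 2
  mean(abs(W - EW) >= abs(sum(rk[seq_len(n1)]) - EW) - 1e-9)
}

# a random unrooted binary tree with full supports
rtree_sup <- function(n, seed, support = "1") {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, tip.label = sprintf("t%02d", 1:n))
  tr$node.label <- rep(support, tr$Nnode)
  tr
}

# restriction helper independent of the package internals
restrict_tree2 <- function(tr, labs) {
  out <- ape::keep.tip(tr, labs)
  if (ape::is.rooted(out) && out$Nnode > 1) out <- ape::unroot(out)
  if (!is.null(out$node.label)) out$node.label <- rep("1", out$Nnode)
  out
}
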