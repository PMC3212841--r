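#' @useDynLib lgtnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
NULL

# ---- newick IO -------------------------------------------------------------

#' Read trees from a newick file
#'
#' Edge supports (posterior probabilities) are expected as internal-node
#' labels, the convention used by Bayesian samplers and by [write_newick()].
#' Trees are returned unrooted; a rooted binary tree is unrooted on input so
#' that every internal edge carries exactly one support value.
#'
#' @param path path to a newick file (one or more trees).
#' @return a list of `phylo` objects.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  validate_newick(txt)
  tr <- ape::read.tree(text = txt)
  if (inherits(tr, "phylo")) tr <- list(tr)
  lapply(tr, function(t) {
    if (anyDuplicated(t$tip.label))
      stop("duplicate leaf label: ",
           t$tip.label[duplicated(t$tip.label)][1])
    if (ape::is.rooted(t) && t$Nnode > 1) t <- ape::unroot(t)
    t
  })
}

# Cheap structural scan so that malformed input fails with the offending
# character offset rather than an opaque parser error.
validate_newick <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unbalanced ')' at character offset ", i)
    }
    if (ch == ";" && depth != 0L)
      stop("malformed newick: ';' inside open group at character offset ", i)
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at character offset ",
         length(chars))
  if (!any(chars == ";"))
    stop("malformed newick: missing ';' terminator at character offset ",
         length(chars))
  invisible(TRUE)
}

#' Write a tree (supports as internal node labels) to a newick file
#' @param tree a `phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---- splits ----------------------------------------------------------------

# Internal representation: a split over the alphabetically sorted taxon set
# is an integer bit mask (bit i-1 = i-th sorted label), normalised to the
# side that excludes the first label.  Masks are comparable across trees
# sharing a taxon set.

bit_count <- function(x) {
  n <- integer(length(x))
  x <- as.integer(x)
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

# Re-index tips so tip i corresponds to sort(labels)[i]; required before any
# mask-space comparison or C++ call involving two trees.
std_edge <- function(tree, labels = sort(tree$tip.label)) {
  ntip <- length(tree$tip.label)
  stopifnot(identical(sort(tree$tip.label), sort(labels)))
  perm <- match(tree$tip.label, labels)
  e <- tree$edge
  istip <- e <= ntip
  e[istip] <- perm[e[istip]]
  e
}

#' Non-trivial splits of a tree with their supports
#'
#' @param tree a `phylo`; internal-node labels, when present, are read as
#'   numeric supports (missing labels count as support 1).
#' @return data.frame with columns `mask` (integer bit mask over the sorted
#'   taxon set, normalised away from the first label), `support`, `size`
#'   (smaller side).  Ordered by mask.
#' @export
tree_splits <- function(tree) {
  labels <- sort(tree$tip.label)
  ntip <- length(labels)
  if (ape::is.rooted(tree) && tree$Nnode > 1) tree <- ape::unroot(tree)
  tree <- stats::reorder(tree, "postorder")
  e <- std_edge(tree, labels)
  nnode <- max(e)
  below <- integer(nnode)
  below[seq_len(ntip)] <- bitwShiftL(1L, seq_len(ntip) - 1L)
  # postorder: every child edge precedes its parent edge
  for (i in seq_len(nrow(e))) below[e[i, 1]] <- bitwOr(below[e[i, 1]], below[e[i, 2]])
  full <- if (ntip >= 31L) stop("taxon sets above 30 leaves not supported") else
    bitwShiftL(1L, ntip) - 1L
  sup <- rep(NA_real_, nnode)
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    sup[ntip + seq_len(tree$Nnode)] <- lab
  }
  keep <- e[, 2] > ntip              # edges subtending internal nodes
  mask <- below[e[keep, 2]]
  support <- sup[e[keep, 2]]
  size <- bit_count(mask)
  ok <- size >= 2L & size <= ntip - 2L
  mask <- mask[ok]; support <- support[ok]
  flip <- bitwAnd(mask, 1L) == 1L
  mask[flip] <- bitwAnd(full, bitwNot(mask[flip]))
  support[is.na(support)] <- 1
  o <- order(mask)
  data.frame(mask = mask[o], support = support[o],
             size = pmin(bit_count(mask[o]), ntip - bit_count(mask[o])))
}

mask_labels <- function(mask, labels) {
  labels[bitwAnd(bitwShiftR(as.integer(mask), seq_along(labels) - 1L), 1L) == 1L]
}

# Two splits (masks over the same taxon set) are compatible iff one of the
# four intersections is empty.
splits_compatible <- function(m1, m2, full) {
  c1 <- bitwAnd(full, bitwNot(m1))
  c2 <- bitwAnd(full, bitwNot(m2))
  bitwAnd(m1, m2) == 0L || bitwAnd(m1, c2) == 0L ||
    bitwAnd(c1, m2) == 0L || bitwAnd(c1, c2) == 0L
}

#' Build a tree from a compatible set of splits
#'
#' The splits (bit masks over `sort(labels)`, normalised away from the first
#' label) must be pairwise compatible; they form a laminar family of
#' clusters once read as "the side away from the first taxon", and the tree
#' is assembled from the containment hierarchy.  Children are emitted in a
#' deterministic order (by smallest leaf label), so equal topologies give
#' byte-identical newick; this is also the package's canonical form.
#'
#' @param labels character vector of taxon labels (any order; sorted
#'   internally).
#' @param masks integer split masks; may be empty (star tree).
#' @param supports optional numeric supports, recycled onto internal nodes.
#' @return a `phylo` object.
#' @export
tree_from_splits <- function(labels, masks, supports = NULL) {
  ape::read.tree(text = newick_from_splits(labels, masks, supports))
}

newick_from_splits <- function(labels, masks, supports = NULL) {
  labels <- sort(labels)
  masks <- as.integer(masks)
  if (is.null(supports)) supports <- rep(NA_real_, length(masks))
  o <- order(-bit_count(masks), masks)
  masks <- masks[o]; supports <- supports[o]
  full <- bitwShiftL(1L, length(labels)) - 1L
  build <- function(members_mask, idx) {
    # idx: indices of clusters strictly contained in members_mask, largest first
    used <- 0L
    parts <- character(0)
    keys <- character(0)
    i <- 1
    while (i <= length(idx)) {
      ci <- idx[i]
      if (bitwAnd(masks[ci], used) == 0L) {
        inner <- idx[idx != ci &
                       bitwAnd(masks[idx], bitwNot(masks[ci])) == 0L]
        sub <- build(masks[ci], inner)
        supstr <- if (is.na(supports[ci])) "" else format(supports[ci])
        parts <- c(parts, paste0(sub$str, supstr))
        keys <- c(keys, sub$min)
        used <- bitwOr(used, masks[ci])
        idx <- setdiff(idx, c(ci, inner))
        i <- 1
      } else i <- i + 1
    }
    rest <- bitwAnd(members_mask, bitwNot(used))
    singles <- mask_labels(rest, labels)
    parts <- c(parts, singles)
    keys <- c(keys, singles)
    o2 <- order(keys)
    list(str = paste0("(", paste(parts[o2], collapse = ","), ")"),
         min = min(keys))
  }
  root <- build(full, seq_along(masks))
  paste0(root$str, ";")
}

#' Canonical newick string of a topology
#'
#' Branch lengths are dropped; supports are kept as node labels.  Two trees
#' have the same canonical newick iff they induce the same split set.
#' @param tree a `phylo`.
#' @export
canonical_newick <- function(tree) {
  sp <- tree_splits(tree)
  newick_from_splits(tree$tip.label, sp$mask,
                     ifelse(sp$support == 1, NA_real_, sp$support))
}

# topology-only key (ignores supports)
topology_key <- function(tree) {
  paste(tree_splits(tree)$mask, collapse = ",")
}

# ---- rooting / collapsing --------------------------------------------------

#' Root a tree on an outgroup edge
#'
#' @param tree a `phylo`.
#' @param outgroup character vector of leaf labels; must sit on one side of
#'   exactly one edge of the unrooted tree.
#' @return a rooted `phylo`; the unrooted bipartition set is unchanged.
#' @export
root_tree <- function(tree, outgroup) {
  if (!all(outgroup %in% tree$tip.label))
    stop("outgroup labels not in tree: ",
         paste(setdiff(outgroup, tree$tip.label), collapse = ", "))
  labels <- sort(tree$tip.label)
  full <- bitwShiftL(1L, length(labels)) - 1L
  m <- sum(bitwShiftL(1L, match(outgroup, labels) - 1L))
  if (length(outgroup) > 1 && length(outgroup) < length(labels) - 1) {
    sp <- tree_splits(tree)
    hit <- sp$mask == m | sp$mask == bitwAnd(full, bitwNot(m))
    if (!any(hit))
      stop("outgroup does not identify an edge (non-monophyletic leaf set)")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Contract poorly supported internal edges
#'
#' Every internal edge with support below `threshold` is contracted;
#' supports exactly at the threshold are retained (inclusive rule).  The
#' leaf set is unchanged.  Branch lengths are not preserved (the collapsed
#' tree is used only topologically).
#'
#' @param tree a `phylo` with supports as internal node labels.
#' @param threshold support threshold in (0, 1].
#' @return a `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  sp <- tree_splits(tree)
  keep <- sp$support >= threshold
  tree_from_splits(tree$tip.label, sp$mask[keep], sp$support[keep])
}
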