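# Matrix representation with parsimony: harvested high-support bipartitions
# become binary characters (one column per occurrence; taxa absent from the
# source family are coded '?'), and the reference tree is the most
# parsimonious tree over that matrix.

#' Harvest well-supported bipartitions into an MRP matrix
#'
#' Every non-trivial bipartition with support at or above `pp_threshold`
#' (inclusive, matching a PP >= 0.95 harvesting rule) contributes one binary
#' character.  Duplicate bipartitions from different families are retained:
#' each occurrence is evidence.  Taxa absent from a family are coded missing
#' in that family's columns.
#'
#' @param trees list of `phylo` objects (taxon sets may differ).
#' @param pp_threshold support threshold in (0, 1].
#' @return an object of class `mrp_matrix`: list with `taxa` (sorted union),
#'   `mat` (character matrix of "0"/"1"/"?"), `support`, `family` (source
#'   index of each column).
#' @export
harvest_bipartitions <- function(trees, pp_threshold = 0.95) {
  stopifnot(pp_threshold > 0, pp_threshold <= 1)
  if (length(trees) == 0) stop("empty tree list")
  taxa <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  cols <- list()
  support <- numeric(0)
  family <- integer(0)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    sp <- tree_splits(tr)
    sp <- sp[sp$support >= pp_threshold, , drop = FALSE]
    if (nrow(sp) == 0) next
    lab <- sort(tr$tip.label)
    for (j in seq_len(nrow(sp))) {
      side <- mask_labels(sp$mask[j], lab)
      col <- rep("?", length(taxa))
      col[taxa %in% lab] <- "0"
      col[taxa %in% side] <- "1"
      cols[[length(cols) + 1]] <- col
      support <- c(support, sp$support[j])
      family <- c(family, i)
    }
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(character(0), nrow = length(taxa), ncol = 0)
  rownames(mat) <- taxa
  structure(list(taxa = taxa, mat = mat, support = support, family = family),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat("MRP matrix:", length(x$taxa), "taxa x", ncol(x$mat), "characters\n")
  invisible(x)
}

#' Export an MRP matrix as relaxed PHYLIP characters
#' @param x an `mrp_matrix`.
#' @param path output file.
#' @export
write_mrp_phylip <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(x$taxa), ncol(x$mat)), con)
  for (i in seq_along(x$taxa))
    writeLines(paste(x$taxa[i], paste(x$mat[i, ], collapse = "")), con)
  invisible(path)
}

mrp_phyDat <- function(x) {
  phangorn::phyDat(x$mat, type = "USER", levels = c("0", "1"),
                   ambiguity = "?")
}

#' Build the MRP supertree
#'
#' Finds a fully resolved tree minimising parsimony length over the
#' harvested bipartition matrix.  The search is hill climbing over SPR
#' rearrangements from a random-addition starting tree, repeated for
#' `restarts` independent starts; equal-score results are tie-broken by the
#' lexicographically smallest canonical newick, so the output is
#' deterministic given `seed`.
#'
#' @param x an `mrp_matrix` (at least 4 taxa, at least 1 character).
#' @param seed integer seed driving the random-addition starts.
#' @param restarts number of random-addition restarts.
#' @return a `phylo` with attribute `pscore` (the parsimony length).
#' @export
build_mrp_supertree <- function(x, seed = 1L, restarts = 10L) {
  stopifnot(inherits(x, "mrp_matrix"))
  if (length(x$taxa) < 4) stop("need at least 4 taxa")
  if (ncol(x$mat) == 0) stop("no harvested bipartitions to work from")
  allmiss <- rowSums(x$mat != "?") == 0
  if (any(allmiss))
    stop("taxa with all-missing characters: ",
         paste(x$taxa[allmiss], collapse = ", "))
  dat <- mrp_phyDat(x)
  best_score <- Inf
  best <- list()
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (r in seq_len(restarts)) {
    start <- phangorn::random.addition(dat)
    fit <- phangorn::optim.parsimony(start, dat, method = "fitch",
                                     rearrangements = "SPR", trace = 0)
    sc <- phangorn::parsimony(fit, dat, method = "fitch")
    if (sc < best_score) {
      best_score <- sc
      best <- list(fit)
    } else if (sc == best_score) best <- c(best, list(fit))
  }
  keys <- vapply(best, canonical_newick, character(1))
  tree <- best[[order(keys)[1]]]
  tree <- ape::unroot(tree)
  tree$node.label <- NULL
  attr(tree, "pscore") <- best_score
  tree
}
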