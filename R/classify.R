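# Integration: the discordance flag and the ORB flag jointly classify each
# gene family, the classification rolls up into 2x2 contingency tables, and
# the association / co-transfer / enrichment analyses run on top.

#' Classify a gene set from its discordance and ORB flags
#'
#' `(discordant, ORB+) -> within_gene_lateral`;
#' `(discordant, ORB-) -> whole_gene_lateral`;
#' `(concordant, ORB+) -> within_gene_lateral` (cryptic within-gene
#' transfer: breakpoints without whole-tree conflict);
#' `(concordant, ORB-) -> vertical`.  An `NA` flag yields `unclassified`,
#' never a silent `vertical`.
#'
#' @param discordant,orb logical vectors (recycled to common length).
#' @return character vector of classes.
#' @export
classify_gene_set <- function(discordant, orb) {
  n <- max(length(discordant), length(orb))
  discordant <- rep_len(discordant, n)
  orb <- rep_len(orb, n)
  out <- rep("unclassified", n)
  ok <- !is.na(discordant) & !is.na(orb)
  out[ok & orb] <- "within_gene_lateral"
  out[ok & !orb & discordant] <- "whole_gene_lateral"
  out[ok & !orb & !discordant] <- "vertical"
  out
}

#' Summarise classified gene sets into a 2x2 contingency table
#'
#' Rows: protein tree discordant / concordant with the reference; columns:
#' ORB+ / ORB-.  Unclassified records (NA flags) are excluded from all
#' denominators.  The lateral count is the union of the discordant and
#' ORB+ families, i.e. everything but the concordant/ORB- cell.
#'
#' @param records data.frame with at least logical columns `discordant`
#'   and `orb`; optionally `regulator_category`.
#' @param category_filter optional value of `regulator_category` to
#'   restrict to.
#' @return an object of class `classification_table`: list with `cells`
#'   (2x2 matrix), `row_totals`, `col_totals`, `total`, `lateral`,
#'   `vertical`, `lateral_prop` (percent), `n_unclassified`.
#' @export
summarize_classification <- function(records, category_filter = NULL) {
  if (!is.null(category_filter))
    records <- records[!is.na(records$regulator_category) &
                         records$regulator_category %in% category_filter, ,
                       drop = FALSE]
  ok <- !is.na(records$discordant) & !is.na(records$orb)
  n_unc <- sum(!ok)
  r <- records[ok, , drop = FALSE]
  if (nrow(r) == 0)
    warning("empty selection: table of zeros")
  cells <- matrix(c(sum(r$discordant & r$orb), sum(r$discordant & !r$orb),
                    sum(!r$discordant & r$orb), sum(!r$discordant & !r$orb)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("discordant", "concordant"),
                                  c("orb_pos", "orb_neg")))
  total <- sum(cells)
  lateral <- total - cells["concordant", "orb_neg"]
  structure(list(cells = cells,
                 row_totals = rowSums(cells),
                 col_totals = colSums(cells),
                 total = total,
                 lateral = lateral,
                 vertical = cells["concordant", "orb_neg"],
                 lateral_prop = if (total > 0) 100 * lateral / total else
                   NA_real_,
                 n_unclassified = n_unc),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  print(x$cells)
  cat(sprintf("total %d; lateral %d (%.1f%%); vertical %d; unclassified %d\n",
              x$total, x$lateral, x$lateral_prop, x$vertical,
              x$n_unclassified))
  invisible(x)
}

#' Fisher's exact association between two groups
#'
#' Two-sided exact hypergeometric test on the 2x2 table formed by
#' (successes, failures) in each group.  The sample odds ratio is reported;
#' when a cell is zero the 0.5-continuity-corrected odds ratio is used and
#' flagged.
#'
#' @param group_a,group_b integer vectors `c(successes, failures)`.
#' @return list with `odds_ratio`, `p`, `continuity` (logical), `table`.
#' @export
fisher_association <- function(group_a, group_b) {
  tab <- rbind(a = as.integer(group_a), b = as.integer(group_b))
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  continuity <- any(tab == 0)
  t2 <- if (continuity) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = unname(or), p = ft$p.value,
       continuity = continuity, table = tab)
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided with tie correction.  The exact null distribution is used for
#' small samples: the standard exact tables when there are no ties, and a
#' direct enumeration of all group assignments of the midranks (two-sided
#' by distance of the rank sum from its null expectation) when there are
#' ties and at most 50000 assignments.  Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param values_a,values_b numeric samples (each size >= 1).
#' @return two-sided p-value.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("empty sample")
  n1 <- length(values_a); n2 <- length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  if (!ties && n1 < 50 && n2 < 50)
    return(stats::wilcox.test(values_a, values_b, exact = TRUE)$p.value)
  if (ties && choose(n1 + n2, n1) <= 50000) {
    rk <- rank(c(values_a, values_b))
    combs <- utils::combn(n1 + n2, n1)
    W <- colSums(matrix(rk[combs], nrow = n1))
    EW <- n1 * (n1 + n2 + 1) / 2
    wobs <- sum(rk[seq_len(n1)])
    return(mean(abs(W - EW) >= abs(wobs - EW) - 1e-9))
  }
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = FALSE,
                       correct = TRUE)$p.value)
}

#' Per-category over/under-representation of a gene subset
#'
#' For every functional category, Fisher's exact test comparing the
#' category's frequency in the subset against the remaining genes, with a
#' direction flag.  No multiple-testing correction is applied; the number
#' of tests performed is reported alongside.
#'
#' @param gene_categories named character vector: category per gene (every
#'   gene has exactly one category).
#' @param subset character vector of gene names (must be drawn from
#'   `names(gene_categories)`).
#' @param alpha significance level for flagging (default 0.05).
#' @return data.frame: category, n_subset, n_background, p, direction
#'   ("over"/"under"), significant; attribute `n_tests`.
#' @export
functional_enrichment <- function(gene_categories, subset, alpha = 0.05) {
  if (!all(subset %in% names(gene_categories)))
    stop("subset genes missing from the background: ",
         paste(utils::head(setdiff(subset, names(gene_categories))),
               collapse = ", "))
  cats <- sort(unique(gene_categories))
  insub <- names(gene_categories) %in% subset
  if (length(subset) == 0) {
    warning("empty subset: nothing to test")
    return(structure(data.frame(category = cats, n_subset = 0L,
                                n_background = as.integer(table(gene_categories)[cats]),
                                p = NA_real_, direction = NA_character_,
                                significant = FALSE),
                     n_tests = 0L))
  }
  out <- lapply(cats, function(cc) {
    incat <- gene_categories == cc
    tab <- matrix(c(sum(insub & incat), sum(insub & !incat),
                    sum(!insub & incat), sum(!insub & !incat)), 2)
    p <- stats::fisher.test(tab)$p.value
    fsub <- tab[1, 1] / sum(tab[, 1])
    fbg <- sum(incat) / length(gene_categories)
    data.frame(category = cc, n_subset = tab[1, 1],
               n_background = sum(incat), p = p,
               direction = if (fsub >= fbg) "over" else "under",
               significant = p < alpha)
  })
  structure(do.call(rbind, out), n_tests = length(cats))
}

#' Co-transfer verdict for a regulatory neighbourhood
#'
#' Tests whether the member gene families of a neighbourhood look like a
#' single co-transferred block: are all members ORB-?  all discordant?  do
#' all member trees support the same evolutionary history (identical
#' collapsed topologies on pairwise shared taxa; `NA` when an overlap has
#' fewer than 4 taxa)?  does the neighbourhood contain at least one
#' observable breakpoint?
#'
#' @param neighbourhood a `regulatory_neighbourhood` (size >= 2).
#' @param records classified gene-set data.frame with columns `family`,
#'   `discordant`, `orb`, and a `gene` column linking records to network
#'   genes.
#' @param trees named list of `phylo` objects keyed by family id.
#' @param threshold support collapse threshold used for the same-history
#'   comparison.
#' @return list with `genes`, `n_with_records`, `all_orb_minus`,
#'   `all_discordant`, `same_history`, `any_breakpoint`,
#'   `co_transfer_candidate`.
#' @export
co_transfer_analysis <- function(neighbourhood, records, trees,
                                 threshold = 0.95) {
  genes <- neighbourhood$genes
  if (length(genes) < 2) stop("neighbourhood of size < 2")
  rec <- records[match(genes, records$gene), , drop = FALSE]
  have <- !is.na(rec$family)
  orb <- rec$orb[have]
  disc <- rec$discordant[have]
  fams <- rec$family[have]
  all_orb_minus <- if (length(orb)) all(!orb, na.rm = FALSE) else NA
  all_disc <- if (length(disc)) all(disc, na.rm = FALSE) else NA
  any_bp <- if (length(orb)) any(orb, na.rm = TRUE) else NA
  same <- NA
  tl <- trees[as.character(fams)]
  tl <- tl[!vapply(tl, is.null, logical(1))]
  if (length(tl) >= 2) {
    cmp <- logical(0)
    for (i in seq_len(length(tl) - 1)) for (j in (i + 1):length(tl)) {
      shared <- intersect(tl[[i]]$tip.label, tl[[j]]$tip.label)
      if (length(shared) < 4) { cmp <- c(cmp, NA); next }
      a <- collapse_low_support(restrict_tree(tl[[i]], shared), threshold)
      b <- collapse_low_support(restrict_tree(tl[[j]], shared), threshold)
      cmp <- c(cmp, topology_key(a) == topology_key(b))
    }
    same <- if (all(is.na(cmp))) NA else all(cmp, na.rm = FALSE)
  }
  list(genes = genes, n_with_records = sum(have),
       all_orb_minus = all_orb_minus, all_discordant = all_disc,
       same_history = same, any_breakpoint = any_bp,
       co_transfer_candidate = isTRUE(all_orb_minus) && isTRUE(all_disc) &&
         isTRUE(same))
}
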