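# Phase 1 of the recombination detector: three site-order-sensitive
# statistics, each judged against a permutation null over site order, with
# the pass rule "at least two of three below alpha".

#' Permutation screen for within-gene phylogenetic discrepancy
#'
#' Computes three statistics on the parsimony-informative sites of a
#' nucleotide alignment and a permutation p-value for each:
#'
#' * `phi` - pairwise homoplasy index: mean refined incompatibility of
#'   pairs of informative sites whose original coordinates are within
#'   `window` bases; recombination makes nearby sites *more* compatible
#'   than a random arrangement, so the p-value is the lower tail.
#' * `nss` - neighbour similarity score: mean agreement between adjacent
#'   rows of the binary site-compatibility matrix; recombination clusters
#'   compatible sites, upper tail.
#' * `maxchi` - maximum chi-squared: for every sequence pair and every cut
#'   point, the 2x2 chi-squared contrasting mismatch densities left and
#'   right of the cut; upper tail of the maximum.
#'
#' The refined incompatibility of two sites is the cyclomatic number of
#' their state-pair graph (0 iff the generalised four-gamete condition
#' holds).  Permutation p-values are `(1 + b) / (1 + n_permutations)` and
#' therefore lie in (0, 1].  Alignments with fewer than two informative
#' sites cannot be tested and fail automatically with all p-values 1.
#'
#' @param aln `nuc_alignment` or character matrix, at least 4 sequences.
#' @param n_permutations permutations of site order (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param alpha per-statistic significance level of the pass rule.
#' @param window PHI proximity window in original coordinates (bases).
#' @return an object of class `screen_result`: list with `p_values` (named
#'   numeric of length 3), `statistics`, `n_informative`, and `passed`
#'   (`TRUE` iff at least two p-values are below `alpha`).
#' @export
incompatibility_screen <- function(aln, n_permutations = 1000L, seed = 1L,
                                   alpha = 0.1, window = 100L) {
  m <- as_alignment_matrix(aln)
  if (nrow(m) < 4) stop("need at least 4 sequences")
  pos <- if (inherits(aln, "nuc_alignment")) aln$column_map else
    seq_len(ncol(m)) - 1L
  enc <- encode_informative(m, pos)
  if (ncol(enc$x) < 2) {
    p <- c(phi = 1, nss = 1, maxchi = 1)
    return(structure(list(p_values = p,
                          statistics = c(phi = NA_real_, nss = NA_real_,
                                         maxchi = NA_real_),
                          n_informative = ncol(enc$x),
                          passed = FALSE, alpha = alpha),
                     class = "screen_result"))
  }
  res <- cpp_screen_stats(enc$x, enc$pos, as.integer(window),
                          as.integer(n_permutations),
                          as.integer(seed) %% .Machine$integer.max)
  p <- c(phi = res$p_phi, nss = res$p_nss, maxchi = res$p_maxchi)
  structure(list(p_values = p,
                 statistics = c(phi = res$phi, nss = res$nss,
                                maxchi = res$maxchi),
                 n_informative = ncol(enc$x),
                 passed = screen_pass(p, alpha), alpha = alpha),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen:", x$n_informative, "informative sites; p =",
      paste(sprintf("%s=%.4g", names(x$p_values), x$p_values),
            collapse = ", "),
      "->", if (x$passed) "PASSED" else "failed", "\n")
  invisible(x)
}

#' Two-of-three pass rule for screen p-values
#' @param p numeric vector of three p-values.
#' @param alpha significance level (default 0.1).
#' @export
screen_pass <- function(p, alpha = 0.1) {
  sum(p < alpha) >= 2
}

# Keep parsimony-informative columns (>= 2 states each seen >= 2 times,
# gaps/ambiguity as missing), coded as integers for the C++ kernel.
encode_informative <- function(m, pos) {
  states <- c(A = 0L, C = 1L, G = 2L, T = 3L, U = 3L)
  x <- matrix(-1L, nrow = nrow(m), ncol = ncol(m))
  up <- toupper(m)
  for (s in names(states)) x[up == s] <- states[[s]]
  informative <- apply(x, 2, function(col) {
    tb <- tabulate(col[col >= 0] + 1L, 4L)
    sum(tb >= 2L) >= 2L
  })
  list(x = x[, informative, drop = FALSE], pos = as.integer(pos[informative]))
}
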