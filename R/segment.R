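# Phase 2 of the recombination detector: assign a candidate topology to
# every alignment segment by a penalized change-point dynamic program over
# per-site log-likelihoods, then grade the breakpoint evidence.

#' Per-site log-likelihoods of candidate topologies
#'
#' Branch lengths of each candidate are optimised on the full alignment
#' under a Jukes-Cantor model (phase 2 needs relative, not absolute, fit);
#' the site log-likelihood matrix drives the segmentation.
#' @param aln `nuc_alignment` or character matrix.
#' @param candidate_topologies list of `phylo` objects covering the
#'   alignment's sequences.
#' @return matrix (candidates x sites) of log-likelihoods.
#' @keywords internal
site_loglik_matrix <- function(aln, candidate_topologies) {
  m <- as_alignment_matrix(aln)
  dat <- phangorn::phyDat(tolower(m), type = "DNA")
  idx <- attr(dat, "index")
  out <- matrix(NA_real_, nrow = length(candidate_topologies), ncol = ncol(m))
  for (k in seq_along(candidate_topologies)) {
    tr <- restrict_tree(candidate_topologies[[k]], rownames(m))
    if (!setequal(tr$tip.label, rownames(m)))
      stop("candidate topology ", k, " does not cover the alignment")
    tr$node.label <- NULL
    if (is.null(tr$edge.length)) tr$edge.length <- rep(0.05, nrow(tr$edge))
    tr$edge.length[tr$edge.length <= 0] <- 1e-6
    fit <- phangorn::pml(tr, dat)
    fit <- phangorn::optim.pml(fit, optEdge = TRUE, model = "JC",
                               control = phangorn::pml.control(trace = 0))
    out[k, ] <- fit$siteLik[idx]
  }
  out
}

#' Segment an alignment into topology-homogeneous blocks
#'
#' Dynamic program maximising total per-site log-likelihood minus
#' `penalty` per topology change.  Breakpoints are reported where the
#' selected topology changes, as 0-based left edges of the right-hand
#' segment; segment support is the likelihood weight of the selected
#' topology within the segment (softmax over candidates of segment total
#' log-likelihoods).
#'
#' @param aln `nuc_alignment` or character matrix.
#' @param candidate_topologies list of 2-20 `phylo` objects; should include
#'   the reference-restricted topology.  Duplicated topologies are removed.
#' @param penalty log-likelihood cost per breakpoint (default 15).
#' @param s_hi,s_lo segment-support thresholds for the A/B/C evidence
#'   classes (see [classify_evidence()]).
#' @return an object of class `breakpoint_call`: list with `positions`
#'   (0-based alignment columns), `positions_orig` (mapped through the
#'   column map), `segment_topologies` (candidate index per segment),
#'   `segment_support`, `segments` (start/end columns, 0-based half-open),
#'   `evidence_class`.
#' @export
segment_alignment <- function(aln, candidate_topologies, penalty = 15,
                              s_hi = 0.95, s_lo = 0.5) {
  if (length(candidate_topologies) == 0) stop("empty candidate set")
  if (length(candidate_topologies) > 20) stop("more than 20 candidates")
  stopifnot(penalty >= 0)
  keys <- vapply(candidate_topologies, topology_key, character(1))
  keep <- !duplicated(keys)
  candidate_topologies <- candidate_topologies[keep]
  m <- as_alignment_matrix(aln)
  cmap <- if (inherits(aln, "nuc_alignment")) aln$column_map else
    seq_len(ncol(m)) - 1L
  K <- length(candidate_topologies)
  S <- ncol(m)
  if (K == 1) {
    return(new_breakpoint_call(integer(0), cmap, rep(1L, 1), 1, S,
                               matrix(0, 1, S), s_hi, s_lo,
                               candidate_topologies))
  }
  L <- site_loglik_matrix(aln, candidate_topologies)
  dp <- matrix(-Inf, K, S)
  choice <- matrix(0L, K, S)       # 0 = stay, j>0 = switch from candidate j
  dp[, 1] <- L[, 1]
  for (s in 2:S) {
    bi <- which.max(dp[, s - 1])
    bv <- dp[bi, s - 1] - penalty
    stay <- dp[, s - 1]
    sw <- stay < bv
    dp[, s] <- L[, s] + ifelse(sw, bv, stay)
    choice[sw, s] <- bi
    choice[bi, s] <- 0L            # best never pays to switch to itself
  }
  z <- integer(S)
  z[S] <- which.max(dp[, S])
  for (s in S:2) z[s - 1] <- if (choice[z[s], s] > 0) choice[z[s], s] else z[s]
  bp <- which(diff(z) != 0)        # 1-based index of last site of left seg
  starts <- c(1L, bp + 1L)
  ends <- c(bp, S)
  seg_topo <- z[starts]
  supp <- vapply(seq_along(starts), function(i) {
    tot <- rowSums(L[, starts[i]:ends[i], drop = FALSE])
    w <- exp(tot - max(tot))
    w[seg_topo[i]] / sum(w)
  }, numeric(1))
  new_breakpoint_call(as.integer(bp), cmap, seg_topo, starts, ends,
                      NULL, s_hi, s_lo, candidate_topologies,
                      support = supp)
}

new_breakpoint_call <- function(bp, cmap, seg_topo, starts, ends, L,
                                s_hi, s_lo, candidates, support = NULL) {
  if (is.null(support)) support <- rep(1, length(seg_topo))
  call <- structure(list(
    positions = as.integer(bp),            # 0-based left edge of right seg
    positions_orig = as.integer(cmap[bp + 1L]),
    segment_topologies = as.integer(seg_topo),
    segment_support = support,
    segments = cbind(start = as.integer(starts) - 1L,
                     end = as.integer(ends)),
    n_candidates = length(candidates),
    evidence_class = "none"), class = "breakpoint_call")
  call$evidence_class <- classify_evidence(call, s_hi = s_hi, s_lo = s_lo)
  call
}

#' @export
print.breakpoint_call <- function(x, ...) {
  cat("breakpoints:", if (length(x$positions)) paste(x$positions, collapse = ", ")
      else "none", " class:", x$evidence_class, "\n")
  invisible(x)
}

#' Grade breakpoint evidence into classes A, B, C or none
#'
#' For each breakpoint the two flanking segments must select distinct
#' (hence, for binary candidates on one leaf set, topologically
#' incompatible) candidates.  Class A requires per-segment likelihood
#' support at least `s_hi` on both flanks, B at least `s_hi` on one and
#' `s_lo` on the other, C at least `s_lo` on both; the call's class is the
#' strongest class achieved by any breakpoint, `none` if there are no
#' breakpoints or no flank pair reaches `s_lo`.
#'
#' @param call a `breakpoint_call`.
#' @param support_profile optional replacement for the call's own
#'   per-segment supports.
#' @param s_hi,s_lo support thresholds.
#' @return one of `"A"`, `"B"`, `"C"`, `"none"`.
#' @export
classify_evidence <- function(call, support_profile = NULL,
                              s_hi = 0.95, s_lo = 0.5) {
  supp <- if (is.null(support_profile)) call$segment_support else
    support_profile
  if (length(call$positions) == 0) return("none")
  best <- "none"
  rank <- c(none = 0, C = 1, B = 2, A = 3)
  for (i in seq_along(call$positions)) {
    if (call$segment_topologies[i] == call$segment_topologies[i + 1]) next
    l <- supp[i]; r <- supp[i + 1]
    cls <- if (l >= s_hi && r >= s_hi) "A"
      else if ((l >= s_hi && r >= s_lo) || (r >= s_hi && l >= s_lo)) "B"
      else if (l >= s_lo && r >= s_lo) "C"
      else "none"
    if (rank[cls] > rank[best]) best <- cls
  }
  best
}

#' Combine phase 1 and phase 2 into the ORB call
#'
#' A gene set is observable-recombination-breakpoint positive (ORB+) iff
#' the permutation screen passed *and* the segmentation produced clear
#' breakpoint evidence (class A, B or C).  Families failing the screen are
#' ORB- regardless of phase 2 (two-phase design: they never reach it).
#'
#' @param screen a `screen_result` (or `NULL` when the screen failed
#'   upstream).
#' @param call a `breakpoint_call` (or `NULL` when phase 2 was not run).
#' @return logical ORB flag.
#' @export
call_orb <- function(screen, call) {
  if (is.null(screen) || !isTRUE(screen$passed)) return(FALSE)
  if (is.null(call)) return(FALSE)
  call$evidence_class %in% c("A", "B", "C")
}
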