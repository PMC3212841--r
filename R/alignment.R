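# Alignments are plain character matrices (rows = strains, one column per
# aligned position).  `nuc_alignment` wraps a matrix together with a map
# from current columns back to original 0-based coordinates, so breakpoint
# positions found after trimming can be reported in untrimmed coordinates.

#' Construct a nucleotide alignment object
#' @param seq character matrix (rows = strains) or named character vector of
#'   equal-length strings.
#' @param column_map integer vector of original 0-based coordinates, one per
#'   column (default identity).
#' @export
nuc_alignment <- function(seq, column_map = NULL) {
  seq <- as_alignment_matrix(seq)
  if (is.null(column_map)) column_map <- seq_len(ncol(seq)) - 1L
  stopifnot(length(column_map) == ncol(seq))
  structure(list(seq = seq, column_map = as.integer(column_map)),
            class = "nuc_alignment")
}

#' @export
print.nuc_alignment <- function(x, ...) {
  cat("alignment:", nrow(x$seq), "sequences x", ncol(x$seq), "columns\n")
  invisible(x)
}

as_alignment_matrix <- function(x) {
  if (inherits(x, "nuc_alignment")) return(x$seq)
  if (is.matrix(x)) return(x)
  if (is.character(x)) {
    if (length(unique(nchar(x))) != 1) stop("sequences have unequal lengths")
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
    return(m)
  }
  stop("unsupported alignment representation")
}

#' Read a FASTA alignment into a character matrix
#' @param path FASTA file of aligned sequences.
#' @export
read_fasta_alignment <- function(path) {
  d <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(d)))
  rownames(m) <- names(d)
  m
}

#' Write a character-matrix alignment as FASTA
#' @param aln matrix or `nuc_alignment`.
#' @param path output file.
#' @export
write_fasta_alignment <- function(aln, path) {
  m <- as_alignment_matrix(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m)))
    writeLines(c(paste0(">", rownames(m)[i]),
                 paste(m[i, ], collapse = "")), con)
  invisible(path)
}

#' Remove ambiguously aligned regions (block trimming)
#'
#' A relaxed Gblocks-style filter.  A column is *conserved* when its most
#' frequent non-gap character occurs in at least
#' `floor(min_conserved_frac * n) + 1` sequences (the default 0.5 gives the
#' (n/2)+1 rule).  Runs of contiguous non-conserved columns longer than
#' `max_nonconserved_run` are rejected; the remaining stretches are trimmed
#' at both ends to flank columns that meet the (identical-by-default) flank
#' requirement, and surviving blocks shorter than `min_block_len` are
#' dropped.  With `allow_all_gaps` (default) gap characters simply do not
#' count towards the majority; otherwise any column containing a gap is
#' non-conserved.
#'
#' @param aln matrix, named character vector, or `nuc_alignment`.
#' @param min_conserved_frac,min_flank_frac fractions of sequences required
#'   for a conserved / flank position.
#' @param max_nonconserved_run longest tolerated run of non-conserved
#'   columns.
#' @param min_block_len minimum retained block length.
#' @param allow_all_gaps keep columns regardless of gap content.
#' @return a `nuc_alignment` holding the concatenated retained blocks, with
#'   `column_map` giving the original 0-based coordinates.  If nothing is
#'   retained an empty alignment is returned with a warning.
#' @export
trim_alignment_blocks <- function(aln, min_conserved_frac = 0.5,
                                  min_flank_frac = 0.5,
                                  max_nonconserved_run = 50L,
                                  min_block_len = 5L,
                                  allow_all_gaps = TRUE) {
  m <- as_alignment_matrix(aln)
  if (ncol(m) == 0) stop("empty alignment")
  orig_map <- if (inherits(aln, "nuc_alignment")) aln$column_map else
    seq_len(ncol(m)) - 1L
  n <- nrow(m)
  need_c <- floor(min_conserved_frac * n) + 1L
  need_f <- floor(min_flank_frac * n) + 1L
  gap <- c("-", ".", "?")
  topcount <- apply(m, 2, function(col) {
    col <- col[!(col %in% gap)]
    if (!length(col)) 0L else max(table(col))
  })
  hasgap <- apply(m, 2, function(col) any(col %in% gap))
  conserved <- topcount >= need_c & (allow_all_gaps | !hasgap)
  flank <- topcount >= need_f & (allow_all_gaps | !hasgap)
  # reject over-long non-conserved runs
  r <- rle(!conserved)
  rejected <- rep(FALSE, ncol(m))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths))
    if (r$values[i] && r$lengths[i] > max_nonconserved_run)
      rejected[starts[i]:ends[i]] <- TRUE
  keep <- rep(FALSE, ncol(m))
  r2 <- rle(rejected)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  for (i in seq_along(r2$lengths)) {
    if (r2$values[i]) next
    idx <- starts[i]:ends[i]
    fl <- idx[flank[idx]]
    if (!length(fl)) next
    block <- min(fl):max(fl)
    if (length(block) >= min_block_len) keep[block] <- TRUE
  }
  if (!any(keep)) {
    warning("no columns retained by block trimming")
    return(nuc_alignment(m[, 0, drop = FALSE], integer(0)))
  }
  nuc_alignment(m[, keep, drop = FALSE], orig_map[keep])
}
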