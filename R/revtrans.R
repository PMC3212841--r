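# Reverse translation: thread each coding sequence back through its aligned
# protein so downstream recombination detection runs on codons.

GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) return(NULL)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  aa
}

#' Reverse-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column becomes one codon triple; protein gaps become
#' `---`.  Every CDS must translate to its aligned protein (gaps excluded);
#' trailing stop codons are tolerated and dropped.
#'
#' @param protein_alignment aligned amino acids (matrix, named strings, or
#'   `nuc_alignment`-like container).
#' @param cds_sequences named character vector of unaligned coding
#'   sequences, names matching the alignment rows.
#' @return a `nuc_alignment` of width `3 * ncol(protein_alignment)`.
#' @export
reverse_translate <- function(protein_alignment, cds_sequences) {
  prot <- as_alignment_matrix(protein_alignment)
  out <- matrix("-", nrow = nrow(prot), ncol = 3 * ncol(prot),
                dimnames = list(rownames(prot), NULL))
  for (i in seq_len(nrow(prot))) {
    name <- rownames(prot)[i]
    if (!name %in% names(cds_sequences))
      stop("no CDS for sequence ", name)
    cds <- cds_sequences[[name]]
    aa <- translate_cds(cds)
    if (is.null(aa))
      stop("CDS length not a multiple of 3 for sequence ", name)
    if (length(aa) && aa[length(aa)] == "*") {
      aa <- aa[-length(aa)]
      cds <- substr(cds, 1, nchar(cds) - 3)
    }
    resid <- which(!(prot[i, ] %in% c("-", ".", "?")))
    if (length(aa) != length(resid))
      stop("CDS/protein length mismatch for sequence ", name, ": ",
           length(aa), " codons vs ", length(resid), " residues")
    bad <- which(aa != toupper(prot[i, resid]) & toupper(prot[i, resid]) != "X" &
                   aa != "X")
    if (length(bad))
      stop("CDS does not translate to aligned protein for sequence ", name,
           " at residue ", resid[bad[1]], " (", aa[bad[1]], " vs ",
           prot[i, resid[bad[1]]], ")")
    cds <- toupper(cds)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    for (k in seq_along(resid)) {
      j <- 3 * (resid[k] - 1)
      out[i, (j + 1):(j + 3)] <- strsplit(codons[k], "")[[1]]
    }
  }
  nuc_alignment(out)
}

#' Translate a codon alignment back to amino acids
#'
#' Inverse of [reverse_translate()] (gap triples map to gaps); mainly used
#' for round-trip checks.
#' @param aln `nuc_alignment` or matrix with width divisible by 3.
#' @export
translate_alignment <- function(aln) {
  m <- as_alignment_matrix(aln)
  stopifnot(ncol(m) %% 3 == 0)
  ncolp <- ncol(m) / 3
  out <- matrix("-", nrow = nrow(m), ncol = ncolp,
                dimnames = list(rownames(m), NULL))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncolp)) {
      cod <- paste(m[i, (3 * j - 2):(3 * j)], collapse = "")
      out[i, j] <- if (grepl("-", cod, fixed = TRUE)) "-" else {
        aa <- GENETIC_CODE[toupper(cod)]
        if (is.na(aa)) "X" else aa
      }
    }
  }
  out
}
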