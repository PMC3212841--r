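# Transcriptional regulatory network: directed gene -> gene graph built
# from RegulonDB-dialect edge lists, with topology metrics and the
# global / neighbour / other regulator classification.

#' Build a transcriptional regulatory network from edge lists
#'
#' Accepts RegulonDB-dialect TSV files (columns: regulator, target, effect,
#' evidence; `#` comment lines skipped) or data.frames with those columns.
#' Regulator entries that are TF protein names are mapped to their encoding
#' gene by lower-casing the first character unless `gene_map` overrides
#' them; a heterodimer TF maps to one node per subunit-encoding gene.
#' Edges touching genes in `exclusion_list` (RNA genes, obsolete genes) are
#' dropped, unmappable regulators are logged and skipped, and duplicate
#' edges are merged.
#'
#' @param tf_gene_edges TF -> target-gene interactions (path or data.frame).
#' @param tf_tf_edges optional TF -> TF interactions, same dialect.
#' @param exclusion_list character vector of gene names to remove.
#' @param gene_map named list mapping a regulator name to one or more
#'   encoding genes (e.g. `list(IHF = c("ihfA", "ihfB"))`).
#' @return an object of class `regulatory_network`: list with `graph`
#'   (igraph), `edges` (data.frame from/to), `nodes`, `tf_set` (out-degree
#'   >= 1), and `skipped` (count of unmappable rows).
#' @export
build_trn <- function(tf_gene_edges, tf_tf_edges = NULL,
                      exclusion_list = character(0),
                      gene_map = list()) {
  e1 <- read_regulon_edges(tf_gene_edges)
  e2 <- if (is.null(tf_tf_edges)) NULL else read_regulon_edges(tf_tf_edges)
  raw <- rbind(e1, e2)
  from <- character(0); to <- character(0); skipped <- 0L
  for (i in seq_len(nrow(raw))) {
    genes <- map_regulator(raw$regulator[i], gene_map)
    tgt <- map_regulator(raw$target[i], gene_map)
    if (is.null(genes) || is.null(tgt)) {
      skipped <- skipped + 1L
      next
    }
    for (g in genes) for (t in tgt) { from <- c(from, g); to <- c(to, t) }
  }
  keep <- !(from %in% exclusion_list) & !(to %in% exclusion_list)
  ed <- unique(data.frame(from = from[keep], to = to[keep],
                          stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(ed, directed = TRUE)
  tf_set <- names(which(igraph::degree(g, mode = "out") > 0))
  if (skipped > 0)
    message(skipped, " edge row(s) skipped: unmappable gene names")
  structure(list(graph = g, edges = ed,
                 nodes = igraph::V(g)$name, tf_set = tf_set,
                 skipped = skipped),
            class = "regulatory_network")
}

read_regulon_edges <- function(x) {
  if (is.data.frame(x)) {
    df <- x
  } else {
    df <- utils::read.table(x, sep = "\t", header = FALSE,
                            comment.char = "#", quote = "",
                            stringsAsFactors = FALSE, fill = TRUE)
  }
  if (ncol(df) < 2) stop("edge table needs at least regulator and target")
  names(df)[1:2] <- c("regulator", "target")
  df[!is.na(df$regulator) & !is.na(df$target) &
       df$regulator != "" & df$target != "", 1:2]
}

map_regulator <- function(name, gene_map) {
  if (!is.null(gene_map[[name]])) return(gene_map[[name]])
  if (grepl("[^A-Za-z0-9_.-]", name)) return(NULL)
  paste0(tolower(substr(name, 1, 1)), substring(name, 2))
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("TRN:", length(x$nodes), "genes,", nrow(x$edges), "interactions,",
      length(x$tf_set), "TF-encoding genes\n")
  invisible(x)
}

#' Out-degree of a node (number of distinct regulated targets)
#' @param net a `regulatory_network`.
#' @param node gene name.
#' @export
out_degree <- function(net, node) {
  if (!node %in% net$nodes) stop("unknown node: ", node)
  unname(igraph::degree(net$graph, v = node, mode = "out"))
}

#' Directed shortest-path betweenness of a node
#'
#' Sum over ordered node pairs of the fraction of shortest directed paths
#' passing through the node.
#' @param net a `regulatory_network`.
#' @param node gene name.
#' @export
node_betweenness <- function(net, node) {
  if (!node %in% net$nodes) stop("unknown node: ", node)
  unname(igraph::betweenness(net$graph, v = node, directed = TRUE))
}

#' Classify global regulators (top-k by out-degree)
#'
#' The `k` TFs regulating the largest numbers of target genes.  A tie
#' across the rank-k boundary includes all tied TFs with a warning, so the
#' result can exceed `k`.  Heterodimer subunit genes each carry the shared
#' target set and are ranked independently.
#'
#' @param net a `regulatory_network`.
#' @param k number of global regulators (default 20).
#' @return character vector of TF gene names.
#' @export
classify_global <- function(net, k = 20L) {
  if (length(net$tf_set) < k) stop("k exceeds the number of TFs")
  deg <- igraph::degree(net$graph, v = net$tf_set, mode = "out")
  deg <- sort(deg, decreasing = TRUE)
  cutoff <- deg[k]
  sel <- names(deg)[deg >= cutoff]
  if (length(sel) > k)
    warning("tie at the rank-", k, " boundary: returning ", length(sel),
            " global regulators")
  sel
}

#' Read a gene-coordinate (locus) table
#'
#' TSV with columns gene, replicon, start, end, strand (header optional,
#' detected).  Chromosome rank indices are assigned from start order within
#' each replicon.
#' @param x path or data.frame.
#' @return data.frame with columns gene, replicon, rank, start, end, strand.
#' @export
read_loci <- function(x) {
  if (is.data.frame(x)) df <- x else {
    first <- readLines(x, n = 1)
    hdr <- grepl("gene", first, ignore.case = TRUE)
    df <- utils::read.table(x, sep = "\t", header = hdr, quote = "",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (!hdr) names(df) <- c("gene", "replicon", "start", "end",
                             "strand")[seq_len(ncol(df))]
  }
  if (!"replicon" %in% names(df)) df$replicon <- "chr"
  if (!"rank" %in% names(df)) {
    df <- df[order(df$replicon, df$start), ]
    df$rank <- stats::ave(df$start, df$replicon,
                          FUN = function(s) seq_along(s))
  }
  rownames(df) <- NULL
  df
}

# circular rank adjacency within a replicon
ranks_adjacent <- function(r1, r2, nmax) {
  d <- abs(r1 - r2)
  d == 1 | d == nmax - 1
}

#' Identify neighbour regulators
#'
#' Non-global TFs that regulate at least one target gene encoded
#' immediately adjacent on the chromosome (rank +/- 1, circular; strand and
#' intergenic distance ignored).  Global regulators with adjacent targets
#' are excluded, as are pairs of adjacent TF genes that regulate each other
#' but no additional adjacent gene (the heterodimer-pair rule).
#' Autoregulation alone never qualifies.  TFs without a locus are skipped
#' with a warning.
#'
#' @param net a `regulatory_network`.
#' @param loci locus table (see [read_loci()]).
#' @param global_set TF genes classified global (see [classify_global()]).
#' @return character vector of neighbour-regulator TF genes.
#' @export
find_neighbour_regulators <- function(net, loci, global_set = character(0)) {
  rank_of <- setNames(loci$rank, loci$gene)
  repl_of <- setNames(loci$replicon, loci$gene)
  nrepl <- table(loci$replicon)
  adj_targets <- function(tf) {
    if (!tf %in% names(rank_of)) return(NULL)
    tg <- setdiff(names(igraph::neighbors(net$graph, tf, mode = "out")), tf)
    tg <- tg[tg %in% names(rank_of) & repl_of[tg] == repl_of[tf]]
    tg[ranks_adjacent(rank_of[tf], rank_of[tg],
                      nrepl[[repl_of[tf]]])]
  }
  missing <- setdiff(net$tf_set, names(rank_of))
  if (length(missing))
    warning("TFs without a locus skipped: ", paste(missing, collapse = ", "))
  cand <- character(0)
  adj <- list()
  for (tf in intersect(net$tf_set, names(rank_of))) {
    a <- adj_targets(tf)
    adj[[tf]] <- a
    if (length(a) && !(tf %in% global_set)) cand <- c(cand, tf)
  }
  # heterodimer-pair rule: adjacent TF pair regulating only each other
  drop <- character(0)
  for (tf in cand) {
    a <- adj[[tf]]
    if (length(a) == 1 && a %in% cand) {
      b <- a
      if (length(adj[[b]]) == 1 && adj[[b]] == tf &&
          ranks_adjacent(rank_of[tf], rank_of[b],
                         nrepl[[repl_of[tf]]]))
        drop <- c(drop, tf, b)
    }
  }
  sort(setdiff(cand, drop))
}

#' Extract the regulatory neighbourhood of a neighbour regulator
#'
#' The maximal contiguous run of rank-adjacent genes regulated by `tf`,
#' extended on both sides of the TF (targets may be upstream or
#' downstream) and truncated at the first unregulated gene; the TF itself
#' is always part of the neighbourhood.
#'
#' @param net a `regulatory_network`.
#' @param loci locus table.
#' @param tf a neighbour-regulator gene.
#' @return an object of class `regulatory_neighbourhood`: list with `tf`,
#'   `targets` (ordered along the chromosome), `genes` (targets plus TF,
#'   chromosome order), `size`.
#' @export
extract_neighbourhood <- function(net, loci, tf) {
  rank_of <- setNames(loci$rank, loci$gene)
  repl <- loci$replicon[match(tf, loci$gene)]
  sub <- loci[loci$replicon == repl, ]
  gene_at <- setNames(sub$gene, sub$rank)
  nmax <- nrow(sub)
  targets <- setdiff(names(igraph::neighbors(net$graph, tf, mode = "out")), tf)
  r0 <- rank_of[[tf]]
  run <- integer(0)
  for (dir in c(1L, -1L)) {
    d <- 1L
    repeat {
      r <- ((r0 + dir * d - 1L) %% nmax) + 1L
      g <- gene_at[[as.character(r)]]
      if (is.null(g) || !(g %in% targets) || r == r0) break
      run <- c(run, r)
      d <- d + 1L
      if (d >= nmax) break
    }
  }
  genes <- gene_at[as.character(sort(unique(c(run, r0))))]
  structure(list(tf = tf,
                 targets = unname(gene_at[as.character(sort(run))]),
                 genes = unname(genes),
                 size = length(run) + 1L),
            class = "regulatory_neighbourhood")
}

#' @export
print.regulatory_neighbourhood <- function(x, ...) {
  cat("neighbourhood of", x$tf, "-", length(x$targets),
      "adjacent target(s):", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}
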