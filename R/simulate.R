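# Synthetic study generator: a species tree, gene families perturbed by
# planted SPR transfers, mosaic alignments with planted breakpoints, and a
# scale-free regulatory network on a circular gene order - every piece with
# ground-truth labels, so the whole pipeline is testable without downloads.

#' Simulation configuration
#'
#' Defaults mirror the scale of the study the package is built around:
#' 27 strains; families of 4-27 members; just over half of the families
#' lateral, of which about a quarter carry an internal breakpoint (total
#' lateral fraction 0.503, breakpoint fraction 0.128); 68.3% of breakpoint
#' families also emit a discordant tree; planted SPR move counts weighted
#' so that most lateral families need one or two moves; a regulatory
#' network of 179 TF genes and 1533 targets with 20 global hubs (hub
#' out-degrees follow the observed top-20 target counts) and 93 neighbour
#' regulators with 1-14 collinear adjacent targets.
#'
#' @param ... overrides for any default listed above.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_strains = 27L,
    n_families = 200L,
    family_size_range = c(4L, 27L),
    lgt_fraction = 0.503,
    breakpoint_fraction = 0.128,
    mosaic_discordant_frac = 0.683,
    spr_move_weights = c(0.46, 0.27, 0.12, 0.07, 0.04,
                         0.02, 0.01, 0.007, 0.003),
    alignment_codons = 200L,
    divergence = 0.1,
    mosaic_divergence = 0.35,
    n_tfs = 179L,
    n_targets = 1533L,
    k_global = 20L,
    n_neighbour = 93L,
    n_global_adjacent = 2L,
    hub_degrees = c(435L, 282L, 225L, 217L, 217L, 158L, 144L, 114L, 97L,
                    85L, 84L, 79L, 79L, 56L, 55L, 49L, 47L, 44L, 40L, 38L),
    hub_scale = 1,
    neighbour_run_weights = c(0.45, 0.2, 0.1, 0.07, 0.05, 0.035, 0.025,
                              0.02, 0.015, 0.01, 0.01, 0.005, 0.005, 0.005),
    seed = 1L)
  override <- list(...)
  stopifnot(all(names(override) %in% names(cfg)))
  cfg[names(override)] <- override
  stopifnot(cfg$lgt_fraction >= 0, cfg$lgt_fraction <= 1,
            cfg$breakpoint_fraction >= 0,
            cfg$breakpoint_fraction <= cfg$lgt_fraction,
            cfg$n_targets >= cfg$n_tfs)
  structure(cfg, class = "sim_config")
}

#' Simulate a species tree
#'
#' Random binary unrooted topology with branch lengths; every internal
#' edge is given support 1.0 (the reference is treated as known).
#' @param n_strains number of strains (>= 4).
#' @param seed integer seed.
#' @export
simulate_species_tree <- function(n_strains, seed = 1L) {
  if (n_strains < 4) stop("need at least 4 strains")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  tr <- ape::rtree(n_strains, rooted = FALSE,
                   tip.label = sprintf("s%02d", seq_len(n_strains)))
  tr$edge.length <- tr$edge.length * 0.1
  tr$node.label <- rep("1", tr$Nnode)
  tr
}

#' Simulate one gene family tree
#'
#' Restricts the species tree to a random taxon subset of the requested
#' size; a lateral family then receives `spr_moves` random SPR operations
#' (each rejected and redrawn if it reproduces the topology it started
#' from).  Supports on internal edges are drawn in \[0.95, 1\] so planted
#' discordance survives a 0.95 support collapse.
#'
#' @param species_tree reference `phylo`.
#' @param size family size (4 .. leaf count).
#' @param lateral logical; transfer planted?
#' @param spr_moves number of planted moves (>= 1 iff `lateral`).
#' @param seed integer seed.
#' @return list with `tree` (a `phylo`) and `truth`
#'   (list: `lateral`, `spr_moves`, `taxa`).
#' @export
simulate_gene_family <- function(species_tree, size, lateral = FALSE,
                                 spr_moves = 0L, seed = 1L) {
  n <- length(species_tree$tip.label)
  if (size < 4 || size > n) stop("size must be between 4 and the leaf count")
  if (spr_moves > 0 && !lateral) stop("spr_moves > 0 requires lateral = TRUE")
  if (lateral && spr_moves < 1) stop("a lateral family needs spr_moves >= 1")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  taxa <- sort(sample(species_tree$tip.label, size))
  tr <- restrict_tree(species_tree, taxa)
  if (lateral) tr <- random_spr_moves(tr, spr_moves)
  tr$node.label <- format(round(runif(tr$Nnode, 0.95, 1), 3))
  list(tree = tr,
       truth = list(lateral = lateral, spr_moves = as.integer(spr_moves),
                    taxa = taxa))
}

#' Simulate a (possibly mosaic) nucleotide alignment
#'
#' Sequences evolve along the given tree(s) under a Jukes-Cantor model
#' (branch lengths scaled by `divergence`).  With `k` breakpoints, `k + 1`
#' trees are required, one per segment; segment boundaries sit exactly at
#' the stated breakpoints (0-based left edges of the right segment).
#'
#' @param trees a `phylo` or list of `phylo` (one per segment).
#' @param length alignment length in columns.
#' @param divergence branch-length multiplier; 0 yields identical
#'   sequences.
#' @param breakpoints integer vector of planted breakpoints (may be empty).
#' @param seed integer seed.
#' @return list with `alignment` (a `nuc_alignment`) and `truth`
#'   (list: `breakpoints`).
#' @export
simulate_alignment <- function(trees, length, divergence = 0.1,
                               breakpoints = integer(0), seed = 1L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  breakpoints <- sort(as.integer(breakpoints))
  if (base::length(trees) != base::length(breakpoints) + 1)
    stop("need one tree per segment")
  bounds <- c(0L, breakpoints, as.integer(length))
  seglen <- diff(bounds)
  if (any(seglen < 30))
    stop("segment shorter than 30 columns (undetectable by design)")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  labels <- sort(trees[[1]]$tip.label)
  segs <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (!setequal(tr$tip.label, labels)) stop("segment trees must share taxa")
    if (divergence <= 0)
      return(matrix("A", nrow = base::length(labels), ncol = seglen[i],
                    dimnames = list(labels, NULL)))
    tr$node.label <- NULL
    if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
    sim <- phangorn::simSeq(tr, l = seglen[i], type = "DNA",
                            rate = divergence)
    m <- toupper(as.character(sim))
    m[labels, , drop = FALSE]
  })
  list(alignment = nuc_alignment(do.call(cbind, segs)),
       truth = list(breakpoints = breakpoints))
}

#' Simulate a transcriptional regulatory network with gene coordinates
#'
#' Genes sit on a circular chromosome.  The `k_global` hub TFs get the
#' configured heavy out-degrees (scaled by `hub_scale`) wired to dispersed
#' targets; `n_neighbour` TFs are planted with a run of 1-14 collinear
#' adjacent targets (run lengths drawn from `neighbour_run_weights`) plus
#' dispersed extras; the remaining TFs are wired strictly distally.
#' `n_global_adjacent` hubs also receive one adjacent target, exercising
#' the rule that global regulators are excluded from the neighbour list.
#' Every non-hub TF draws a Pareto-tailed out-degree capped below the
#' smallest hub degree, so the top-k recovery has no boundary tie.
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return list with `trn` (a `regulatory_network`), `loci` (locus table),
#'   and `truth` (list: `tf_category` named vector with levels global /
#'   neighbour / other, `neighbour_runs` named run lengths).
#' @export
simulate_trn <- function(config = sim_config(), seed = config$seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n_genes <- config$n_tfs + config$n_targets
  genes <- sprintf("g%04d", seq_len(n_genes))
  # evenly spaced TF positions keep planted runs from colliding
  tf_rank <- floor(seq(1, n_genes, length.out = config$n_tfs + 1))[-1]
  tfs <- genes[tf_rank]
  hubs <- tfs[seq_len(config$k_global)]
  non_hub <- setdiff(tfs, hubs)
  neighbour_tfs <- non_hub[seq_len(config$n_neighbour)]
  other_tfs <- setdiff(non_hub, neighbour_tfs)
  if (config$n_tfs < config$k_global + config$n_neighbour)
    stop("n_tfs must cover k_global + n_neighbour")
  # cap degrees by the dispersed-target pool available at this network size
  pool_cap <- max(1L, n_genes - 33L)
  hub_deg <- pmin(pool_cap, pmax(1L, round(config$hub_degrees * config$hub_scale)))
  # Pareto-tailed non-hub degrees, capped below the smallest hub degree
  nh <- length(non_hub)
  nh_deg <- pmin(min(hub_deg) - 1L,
                 pmax(1L, floor(runif(nh)^(-1 / 1.5))))
  rank_of <- setNames(seq_len(n_genes), genes)
  circ <- function(r) ((r - 1L) %% n_genes) + 1L
  distal_pool <- function(r0, exclude_halo) {
    d <- pmin(abs(rank_of - r0), n_genes - abs(rank_of - r0))
    genes[d >= exclude_halo]
  }
  from <- character(0); to <- character(0)
  runs <- integer(0)
  add_edges <- function(tf, targets) {
    from <<- c(from, rep(tf, length(targets)))
    to <<- c(to, targets)
  }
  for (i in seq_along(hubs)) {
    tf <- hubs[i]
    r0 <- rank_of[[tf]]
    adj <- if (i <= config$n_global_adjacent) genes[circ(r0 + 1L)] else
      character(0)
    pool <- setdiff(distal_pool(r0, 16L), tf)
    add_edges(tf, c(adj, sample(pool, hub_deg[i] - length(adj))))
  }
  for (i in seq_along(neighbour_tfs)) {
    tf <- neighbour_tfs[i]
    r0 <- rank_of[[tf]]
    len <- sample(seq_along(config$neighbour_run_weights), 1,
                  prob = config$neighbour_run_weights)
    side <- sample(c(1L, -1L), 1)
    run <- genes[circ(r0 + side * seq_len(len))]
    runs[tf] <- len
    deg <- max(nh_deg[i], len)
    pool <- setdiff(distal_pool(r0, 16L), tf)
    extra <- min(deg - len, length(pool))
    add_edges(tf, c(run, if (extra > 0) sample(pool, extra)))
  }
  for (i in seq_along(other_tfs)) {
    tf <- other_tfs[i]
    pool <- setdiff(distal_pool(rank_of[[tf]], 16L), tf)
    add_edges(tf, sample(pool, min(nh_deg[config$n_neighbour + i],
                                   length(pool))))
  }
  trn <- build_trn(data.frame(regulator = from, target = to,
                              stringsAsFactors = FALSE))
  loci <- data.frame(gene = genes, replicon = "chr",
                     rank = seq_len(n_genes),
                     start = (seq_len(n_genes) - 1L) * 1200L,
                     end = (seq_len(n_genes) - 1L) * 1200L + 900L,
                     strand = sample(c("+", "-"), n_genes, replace = TRUE),
                     stringsAsFactors = FALSE)
  category <- setNames(rep("other", length(tfs)), tfs)
  category[hubs] <- "global"
  category[neighbour_tfs] <- "neighbour"
  list(trn = trn, loci = loci,
       truth = list(tf_category = category, neighbour_runs = runs))
}

#' Simulate a full study cohort
#'
#' Families are assigned planted classes by the configured fractions:
#' mosaic (within-gene lateral, one internal breakpoint between two
#' topologies separated by planted SPR moves), whole-gene lateral
#' (SPR-perturbed tree, homogeneous alignment), or vertical.  A mosaic
#' family emits the perturbed topology as its gene tree with probability
#' `mosaic_discordant_frac`, otherwise the concordant one (cryptic
#' within-gene transfer).  TF genes of the regulatory network are linked to
#' families (TF i to family i while families last), giving each family a
#' regulator category.
#'
#' @param config a `sim_config`.
#' @return list of class `sim_cohort` with `species_tree`, `families`
#'   (per-family list: `id`, `tree`, `alignment`), `truth` (data.frame),
#'   `trn`, `loci`, `tf_truth`, `gene_map`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  seed <- as.integer(config$seed)
  species <- simulate_species_tree(config$n_strains, seed)
  net <- simulate_trn(config, seed + 1L)
  n <- config$n_families
  n_mosaic <- round(config$breakpoint_fraction * n)
  n_whole <- round((config$lgt_fraction - config$breakpoint_fraction) * n)
  classes <- c(rep("within_gene_lateral", n_mosaic),
               rep("whole_gene_lateral", n_whole),
               rep("vertical", n - n_mosaic - n_whole))
  set.seed(seed + 2L)
  classes <- sample(classes)
  lo <- config$family_size_range[1]
  hi <- min(config$family_size_range[2], config$n_strains)
  big <- max(lo, hi - 7L)
  sizes <- ifelse(runif(n) < 0.6, sample(big:hi, n, replace = TRUE),
                  sample(lo:hi, n, replace = TRUE))
  L <- 3L * config$alignment_codons
  fam_seeds <- sample.int(1e7, 2 * n)
  families <- vector("list", n)
  truth <- vector("list", n)
  tf_genes <- names(net$truth$tf_category)
  for (i in seq_len(n)) {
    id <- sprintf("fam%03d", i)
    cls <- classes[i]
    moves <- if (cls == "vertical") 0L else
      sample(seq_along(config$spr_move_weights), 1,
             prob = config$spr_move_weights)
    if (cls == "within_gene_lateral") moves <- min(moves, 2L)
    fam <- simulate_gene_family(species, sizes[i],
                                lateral = cls != "vertical",
                                spr_moves = moves, seed = fam_seeds[i])
    bp <- integer(0)
    if (cls == "within_gene_lateral") {
      base <- restrict_tree(species, fam$truth$taxa)
      perturbed <- fam$tree
      emit_disc <- runif(1) < config$mosaic_discordant_frac
      main <- if (emit_disc) perturbed else base
      minor <- if (emit_disc) base else perturbed
      bp <- as.integer(round(runif(1, 0.35, 0.65) * L))
      aln <- simulate_alignment(list(main, minor), L,
                                divergence = config$mosaic_divergence,
                                breakpoints = bp,
                                seed = fam_seeds[n + i])
      tree <- main
      tree$node.label <- fam$tree$node.label
    } else {
      emit_disc <- cls != "vertical"
      aln <- simulate_alignment(fam$tree, L, divergence = config$divergence,
                                seed = fam_seeds[n + i])
      tree <- fam$tree
    }
    families[[i]] <- list(id = id, tree = tree, alignment = aln$alignment)
    truth[[i]] <- data.frame(
      family = id, size = sizes[i], lgt_class = cls,
      spr_moves = moves,
      breakpoint = if (length(bp)) bp else NA_integer_,
      emit_discordant = emit_disc, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  nmap <- min(length(tf_genes), n)
  gene_map <- data.frame(gene = tf_genes[seq_len(nmap)],
                         family = truth$family[seq_len(nmap)],
                         stringsAsFactors = FALSE)
  truth$gene <- gene_map$gene[match(truth$family, gene_map$family)]
  truth$category <- net$truth$tf_category[truth$gene]
  truth$category[is.na(truth$category)] <- "non-TF"
  names(families) <- truth$family
  structure(list(species_tree = species, families = families,
                 truth = truth, trn = net$trn, loci = net$loci,
                 tf_truth = net$truth, gene_map = gene_map,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("synthetic cohort:", length(x$families), "families,",
      x$config$n_strains, "strains;",
      sum(x$truth$lgt_class != "vertical"), "lateral (",
      sum(x$truth$lgt_class == "within_gene_lateral"), "with breakpoints )\n")
  invisible(x)
}

#' Write a cohort to disk in the formats the pipeline consumes
#'
#' Newick gene trees, FASTA alignments, RegulonDB-style edge list, locus
#' table and a ground-truth TSV.
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  trees <- lapply(cohort$families, `[[`, "tree")
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file.path(dir, "gene_trees.nwk"))
  for (f in cohort$families)
    write_fasta_alignment(f$alignment,
                          file.path(dir, "alignments",
                                    paste0(f$id, ".fasta")))
  utils::write.table(cohort$trn$edges, file.path(dir, "network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$loci, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
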