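# Orchestration: one declarative config drives simulate -> reference ->
# discordance/edit distance -> screen -> breakpoints -> classification ->
# network overlay -> reports.  Every stage is an exported function and can
# be run and composed on its own; run_pipeline() wires them in the
# standard order and writes TSV/JSON outputs.

#' Pipeline configuration
#'
#' Every threshold the method prints is a named key: `pp_threshold` (0.95,
#' bipartition harvest), `collapse_threshold` (0.95, support collapse),
#' `screen_alpha` (0.1, per-statistic screen level), `n_permutations`
#' (1000), `enrichment_alpha` (0.05), `k_global` (20), `d_max` (6, SPR
#' search budget), `s_hi`/`s_lo` (0.95/0.5, breakpoint evidence classes),
#' `penalty` (15, per-breakpoint log-likelihood cost), `phi_window` (100),
#' `max_nodes` (SPR search node cap), `seed`, and `sim` (a [sim_config()]
#' describing the synthetic inputs).
#'
#' @param ... overrides for any key.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(pp_threshold = 0.95, collapse_threshold = 0.95,
              screen_alpha = 0.1, n_permutations = 1000L,
              enrichment_alpha = 0.05, k_global = 20L, d_max = 6L,
              max_nodes = 1e6, s_hi = 0.95, s_lo = 0.5, penalty = 15,
              phi_window = 100L, seed = 1L, sim = sim_config(),
              out_dir = NULL)
  override <- list(...)
  stopifnot(all(names(override) %in% names(cfg)))
  cfg[names(override)] <- override
  stopifnot(cfg$pp_threshold > 0, cfg$pp_threshold <= 1,
            cfg$screen_alpha >= 0, cfg$screen_alpha <= 1,
            cfg$d_max >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Detect discordance and edit distance for a set of families
#'
#' @param trees named list of gene trees.
#' @param reference reference `phylo`.
#' @param config a `pipeline_config`.
#' @return data.frame: family, size, discordant, edit_distance, resolved.
#' @export
detect_discordance <- function(trees, reference, config = pipeline_config()) {
  out <- lapply(names(trees), function(id) {
    tr <- trees[[id]]
    n <- length(tr$tip.label)
    disc <- tryCatch(
      is_discordant(tr, reference, config$collapse_threshold),
      error = function(e) NA)
    dist <- NA_integer_; resolved <- NA
    if (isTRUE(disc)) {
      tst <- collapse_low_support(
        restrict_tree(tr, intersect(tr$tip.label, reference$tip.label)),
        config$collapse_threshold)
      res <- spr_edit_distance(tst, reference, d_max = config$d_max,
                               max_nodes = config$max_nodes)
      dist <- res$distance; resolved <- res$resolved
    } else if (isFALSE(disc)) {
      dist <- 0L; resolved <- TRUE
    }
    data.frame(family = id, size = n, discordant = disc,
               edit_distance = dist, resolved = resolved,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Candidate topologies for segmentation: the reference restricted to the
# family, the family's own tree, and neighbour-joining trees from the
# alignment thirds (sliding-window candidates).
candidate_topologies <- function(aln, tree, reference) {
  m <- as_alignment_matrix(aln)
  cands <- list()
  shared <- intersect(rownames(m), reference$tip.label)
  if (length(shared) == nrow(m))
    cands <- c(cands, list(restrict_tree(reference, rownames(m))))
  cands <- c(cands, list(tree))
  L <- ncol(m)
  thirds <- list(1:floor(L / 3), (floor(L / 3) + 1):floor(2 * L / 3),
                 (floor(2 * L / 3) + 1):L)
  for (idx in thirds) {
    nj <- tryCatch({
      d <- ape::dist.dna(ape::as.DNAbin(tolower(m[, idx, drop = FALSE])),
                         model = "JC69", pairwise.deletion = TRUE)
      if (any(!is.finite(d))) NULL else ape::unroot(ape::nj(d))
    }, error = function(e) NULL)
    if (!is.null(nj)) cands <- c(cands, list(nj))
  }
  cands
}

#' Detect within-gene recombination for one family
#'
#' Phase 1 permutation screen; phase 2 segmentation only when the screen
#' passes (two-phase design).
#' @param aln `nuc_alignment`.
#' @param tree the family's gene tree.
#' @param reference reference `phylo`.
#' @param config a `pipeline_config`.
#' @param seed per-family seed for the permutation stream.
#' @return list with `screen`, `call` (or `NULL`), `orb`.
#' @export
detect_breakpoints <- function(aln, tree, reference,
                               config = pipeline_config(),
                               seed = config$seed) {
  screen <- incompatibility_screen(aln, config$n_permutations, seed = seed,
                                   alpha = config$screen_alpha,
                                   window = config$phi_window)
  call <- NULL
  if (screen$passed) {
    cands <- candidate_topologies(aln, tree, reference)
    call <- segment_alignment(aln, cands, penalty = config$penalty,
                              s_hi = config$s_hi, s_lo = config$s_lo)
  }
  list(screen = screen, call = call, orb = call_orb(screen, call))
}

#' Classify the TF genes of a network as global / neighbour / other
#'
#' @param trn a `regulatory_network`.
#' @param loci locus table.
#' @param k number of global regulators.
#' @return named character vector over `trn$tf_set`.
#' @export
classify_regulators <- function(trn, loci, k = 20L) {
  glob <- classify_global(trn, k)
  neigh <- find_neighbour_regulators(trn, loci, global_set = glob)
  category <- setNames(rep("other", length(trn$tf_set)), trn$tf_set)
  category[glob] <- "global"
  category[neigh] <- "neighbour"
  category
}

#' Run the full pipeline on a (simulated or supplied) cohort
#'
#' Stages, in the standard order: synthetic cohort generation (unless
#' `cohort` is supplied), bipartition harvest and MRP reference tree,
#' per-family discordance and SPR edit distance, two-phase breakpoint
#' detection, gene-set classification with the 2x2 summary tables,
#' regulator classification and neighbourhood co-transfer verdicts, and
#' the association tests (ORB+ enrichment of neighbour regulators against
#' both background variants, edit-distance rank-sum of ORB+ vs ORB-,
#' regulator-count rank-sum of lateral vs vertical genes).  When
#' `config$out_dir` is set, all tables plus a JSON summary and a log of
#' every threshold and seed are written there.
#'
#' @param config a `pipeline_config`.
#' @param cohort optional `sim_cohort` (default: simulate from
#'   `config$sim`, with `config$seed` overriding its seed).
#' @return (invisibly) list with `records`, `tables`, `reference`,
#'   `tf_category`, `neighbourhoods`, `verdicts`, `tests`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (is.null(cohort)) {
    sim <- config$sim
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
  }
  trees <- lapply(cohort$families, `[[`, "tree")
  mrp <- harvest_bipartitions(trees, config$pp_threshold)
  reference <- build_mrp_supertree(mrp, seed = config$seed)
  disc <- detect_discordance(trees, reference, config)
  orb <- logical(nrow(disc)); evid <- character(nrow(disc))
  screens <- vector("list", nrow(disc))
  for (i in seq_len(nrow(disc))) {
    f <- cohort$families[[disc$family[i]]]
    bp <- detect_breakpoints(f$alignment, f$tree, reference, config,
                             seed = config$seed + i)
    orb[i] <- bp$orb
    evid[i] <- if (is.null(bp$call)) "none" else bp$call$evidence_class
    screens[[i]] <- bp$screen
  }
  records <- disc
  records$orb <- orb
  records$evidence_class <- evid
  records$gene <- cohort$gene_map$gene[match(records$family,
                                             cohort$gene_map$family)]
  tf_category <- classify_regulators(cohort$trn, cohort$loci,
                                     config$k_global)
  records$regulator_category <- tf_category[records$gene]
  records$regulator_category[is.na(records$regulator_category) &
                               !is.na(records$gene)] <- "non-TF"
  records$regulator_category[is.na(records$gene)] <- "non-TF"
  records$lgt_class <- classify_gene_set(records$discordant, records$orb)
  tables <- list(
    overall = summarize_classification(records),
    global = summarize_classification(records, "global"),
    neighbour = summarize_classification(records, "neighbour"),
    other = summarize_classification(records, "other"))
  neigh_tfs <- names(tf_category)[tf_category == "neighbour"]
  neighbourhoods <- lapply(neigh_tfs, function(tf)
    extract_neighbourhood(cohort$trn, cohort$loci, tf))
  names(neighbourhoods) <- neigh_tfs
  rec_g <- records
  verdicts <- lapply(neighbourhoods, function(nb)
    tryCatch(co_transfer_analysis(nb, rec_g, trees,
                                  config$collapse_threshold),
             error = function(e) NULL))
  tests <- association_tests(records)
  summary <- list(
    seed = config$seed,
    n_families = nrow(records),
    n_discordant = sum(records$discordant, na.rm = TRUE),
    n_orb_pos = sum(records$orb, na.rm = TRUE),
    n_lateral = tables$overall$lateral,
    lateral_prop = tables$overall$lateral_prop,
    n_unresolved = sum(!records$resolved, na.rm = TRUE),
    tf_categories = as.list(table(tf_category)),
    tests = tests)
  res <- list(records = records, tables = tables, reference = reference,
              tf_category = tf_category, neighbourhoods = neighbourhoods,
              verdicts = verdicts, tests = tests, summary = summary,
              screens = screens, cohort = cohort)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  invisible(res)
}

association_tests <- function(records) {
  ok <- !is.na(records$discordant) & !is.na(records$orb)
  r <- records[ok, , drop = FALSE]
  neigh <- r$regulator_category == "neighbour"
  out <- list(n_tests = 4L)
  orbn <- function(sel) c(sum(r$orb[sel]), sum(!r$orb[sel]))
  both_orb <- sum(r$orb) > 0 && sum(!r$orb) > 0
  if (both_orb && any(neigh) && any(!neigh))
    out$fisher_neighbour_orb_all <-
      fisher_association(orbn(neigh), orbn(!neigh))$p
  nonglob <- !neigh & r$regulator_category != "global"
  if (both_orb && any(neigh) && any(nonglob))
    out$fisher_neighbour_orb_nonglobal <-
      fisher_association(orbn(neigh), orbn(nonglob))$p
  ed <- r$edit_distance
  a <- ed[r$orb & !is.na(ed) & r$discordant]
  b <- ed[!r$orb & !is.na(ed) & r$discordant]
  if (length(a) && length(b))
    out$ranksum_edit_distance_orb <- rank_sum_compare(a, b)
  out
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(res$records, "records.tsv")
  tabs <- do.call(rbind, lapply(names(res$tables), function(nm) {
    t <- res$tables[[nm]]
    data.frame(selection = nm,
               disc_orb_pos = t$cells[1, 1], disc_orb_neg = t$cells[1, 2],
               conc_orb_pos = t$cells[2, 1], conc_orb_neg = t$cells[2, 2],
               total = t$total, lateral = t$lateral,
               lateral_prop = t$lateral_prop)
  }))
  wt(tabs, "classification_tables.tsv")
  wt(data.frame(gene = names(res$tf_category),
                category = unname(res$tf_category)),
     "tf_categories.tsv")
  nb <- do.call(rbind, lapply(res$neighbourhoods, function(x)
    data.frame(tf = x$tf, size = x$size,
               targets = paste(x$targets, collapse = ","))))
  if (!is.null(nb)) wt(nb, "neighbourhoods.tsv")
  vd <- do.call(rbind, lapply(names(res$verdicts), function(nm) {
    v <- res$verdicts[[nm]]
    if (is.null(v)) return(NULL)
    data.frame(tf = nm, n_with_records = v$n_with_records,
               all_orb_minus = v$all_orb_minus,
               all_discordant = v$all_discordant,
               same_history = v$same_history,
               any_breakpoint = v$any_breakpoint,
               co_transfer_candidate = v$co_transfer_candidate)
  }))
  if (!is.null(vd)) wt(vd, "co_transfer_verdicts.tsv")
  jsonlite::write_json(res$summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- c(paste0("seed=", config$seed),
           paste0(names(config)[!vapply(config, is.list, logical(1))], "=",
                  vapply(config[!vapply(config, is.list, logical(1))],
                         function(x) paste(format(x), collapse = ","),
                         character(1))))
  writeLines(log, file.path(config$out_dir, "run.log"))
  invisible(config$out_dir)
}
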