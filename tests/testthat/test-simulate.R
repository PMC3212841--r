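test_that("species trees have the right shape and are seed-deterministic", {
  t27 <- simulate_species_tree(27, 5)
  expect_equal(nrow(tree_splits(t27)), 24)       # n - 3 internal edges
  t4 <- simulate_species_tree(4, 5)
  expect_equal(nrow(tree_splits(t4)), 1)
  expect_identical(ape::write.tree(simulate_species_tree(27, 5)),
                   ape::write.tree(t27))
  expect_error(simulate_species_tree(3), "at least 4")
})

test_that("gene family simulation honours its flags", {
  sp <- simulate_species_tree(20, 9)
  fam <- simulate_gene_family(sp, 10, lateral = FALSE, seed = 2)
  expect_false(is_discordant(fam$tree, sp))
  expect_length(fam$tree$tip.label, 10)
  lat <- simulate_gene_family(sp, 10, lateral = TRUE, spr_moves = 1, seed = 3)
  expect_true(is_discordant(lat$tree, sp))
  expect_equal(spr_edit_distance(lat$tree, sp)$distance, 1L)
  expect_error(simulate_gene_family(sp, 10, lateral = FALSE, spr_moves = 2),
               "requires lateral")
  expect_error(simulate_gene_family(sp, 10, lateral = TRUE, spr_moves = 0),
               "needs spr_moves")
  expect_error(simulate_gene_family(sp, 3), "between 4")
})

test_that("planted supports survive the collapse threshold", {
  sp <- simulate_species_tree(15, 9)
  fam <- simulate_gene_family(sp, 12, lateral = TRUE, spr_moves = 2, seed = 4)
  sup <- as.numeric(fam$tree$node.label)
  expect_true(all(sup >= 0.95, na.rm = TRUE))
  col <- collapse_low_support(fam$tree, 0.95)
  expect_equal(nrow(tree_splits(col)), nrow(tree_splits(fam$tree)))
})

test_that("alignment simulation places segments at the stated breakpoints", {
  sp <- simulate_species_tree(10, 3)
  base <- restrict_tree2(sp, sp$tip.label[1:8])
  pert <- random_spr_moves(base, 2)
  a <- simulate_alignment(list(base, pert), 300, divergence = 0.3,
                          breakpoints = 120L, seed = 6)
  expect_equal(ncol(a$alignment$seq), 300)
  expect_equal(a$truth$breakpoints, 120L)
  expect_error(simulate_alignment(list(base, pert), 300, breakpoints = 280L),
               "shorter than 30")
  expect_error(simulate_alignment(base, 300, breakpoints = 100L),
               "one tree per segment")
})

test_that("zero divergence yields identical sequences that auto-fail the screen", {
  sp <- simulate_species_tree(8, 3)
  a <- simulate_alignment(restrict_tree2(sp, sp$tip.label), 120,
                          divergence = 0, seed = 1)
  expect_equal(length(unique(apply(a$alignment$seq, 1, paste, collapse = ""))),
               1)
  s <- incompatibility_screen(a$alignment, n_permutations = 50, seed = 1)
  expect_false(s$passed)
})

test_that("the cohort is byte-deterministic given its seed", {
  cfg <- sim_config(n_families = 12, n_strains = 10, n_tfs = 20,
                    n_targets = 120, k_global = 4, n_neighbour = 8, seed = 7)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(lapply(c1$families, function(f) ape::write.tree(f$tree)),
                   lapply(c2$families, function(f) ape::write.tree(f$tree)))
  expect_identical(c1$families[[3]]$alignment$seq,
                   c2$families[[3]]$alignment$seq)
  expect_identical(c1$trn$edges, c2$trn$edges)
  expect_identical(c1$truth, c2$truth)
})

test_that("ground-truth labels are internally consistent", {
  cfg <- sim_config(n_families = 30, n_strains = 12, n_tfs = 20,
                    n_targets = 120, k_global = 4, n_neighbour = 8, seed = 8)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  expect_true(all(!is.na(tr$breakpoint[tr$lgt_class == "within_gene_lateral"])))
  expect_true(all(is.na(tr$breakpoint[tr$lgt_class != "within_gene_lateral"])))
  expect_true(all(tr$spr_moves[tr$lgt_class != "vertical"] >= 1))
  expect_true(all(tr$spr_moves[tr$lgt_class == "vertical"] == 0))
  expect_true(all(tr$size >= 4 & tr$size <= 12))
})

test_that("planted TRN structure is recovered by the classifiers", {
  cfg <- sim_config(n_tfs = 30, n_targets = 220, k_global = 5,
                    n_neighbour = 12)
  sim <- simulate_trn(cfg, seed = 11)
  cats <- classify_regulators(sim$trn, sim$loci, k = 5)
  truth <- sim$truth$tf_category
  expect_identical(unname(cats[names(truth)]), unname(truth))
  # every planted neighbour is recovered; no distal-only TF is
  nb <- find_neighbour_regulators(sim$trn, sim$loci,
                                  global_set = classify_global(sim$trn, 5))
  expect_setequal(nb, names(truth)[truth == "neighbour"])
  # neighbourhood sizes equal the planted runs (+1 for the TF)
  for (tf in nb[1:5]) {
    x <- extract_neighbourhood(sim$trn, sim$loci, tf)
    expect_equal(x$size, unname(sim$truth$neighbour_runs[tf]) + 1L)
  }
})

test_that("the hub share of edges grows with the degree-tail weight", {
  share <- vapply(c(0.3, 1, 2.5), function(hs) {
    sim <- simulate_trn(sim_config(n_tfs = 30, n_targets = 300, k_global = 5,
                                   n_neighbour = 12, hub_scale = hs),
                        seed = 13)
    hubs <- names(sim$truth$tf_category)[sim$truth$tf_category == "global"]
    sum(sim$trn$edges$from %in% hubs) / nrow(sim$trn$edges)
  }, numeric(1))
  expect_true(all(diff(share) > 0))
})
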