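toy_edges <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(regulator = m[, 1], target = m[, 2], stringsAsFactors = FALSE)
}

toy_loci <- function(genes) {
  data.frame(gene = genes, replicon = "chr", rank = seq_along(genes),
             start = (seq_along(genes) - 1) * 1000,
             end = (seq_along(genes) - 1) * 1000 + 800, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("duplicate edges are merged", {
  net <- build_trn(toy_edges("a", "b", "a", "c", "a", "b"))
  expect_equal(nrow(net$edges), 2)
  expect_equal(out_degree(net, "a"), 2)
})

test_that("excluded (RNA/obsolete) genes drop their edges", {
  net <- build_trn(toy_edges("a", "b", "a", "rnaX", "b", "c"),
                   exclusion_list = "rnaX")
  expect_equal(nrow(net$edges), 2)
  expect_false("rnaX" %in% net$nodes)
})

test_that("heterodimer TFs contribute one node per subunit gene", {
  ed <- toy_edges("IHF", "t1", "IHF", "t2", "IHF", "t3", "IHF", "t4",
                  "IHF", "t5")
  net <- build_trn(ed, gene_map = list(IHF = c("ihfA", "ihfB")))
  expect_equal(out_degree(net, "ihfA"), 5)
  expect_equal(out_degree(net, "ihfB"), 5)
  expect_true(all(c("ihfA", "ihfB") %in% net$tf_set))
})

test_that("unmappable regulator names are skipped and counted", {
  ed <- toy_edges("a", "b", "bad name!", "c")
  expect_message(net <- build_trn(ed), "1 edge row")
  expect_equal(net$skipped, 1L)
  expect_equal(nrow(net$edges), 1)
})

test_that("star and chain metrics match hand enumeration", {
  star <- build_trn(toy_edges("hub", "x1", "hub", "x2", "hub", "x3"))
  expect_equal(out_degree(star, "hub"), 3)
  expect_equal(node_betweenness(star, "x1"), 0)      # sinks route nothing
  chain <- build_trn(toy_edges("a", "b", "b", "c"))
  expect_equal(node_betweenness(chain, "b"), 1)      # only a->c via b
  expect_equal(out_degree(chain, "c"), 0)
  expect_error(out_degree(chain, "zz"), "unknown node")
  expect_error(node_betweenness(chain, "zz"), "unknown node")
})

test_that("sum of out-degrees equals the edge count", {
  net <- simulate_trn(sim_config(n_tfs = 25, n_targets = 160, k_global = 4,
                                 n_neighbour = 10), seed = 8)$trn
  degs <- vapply(net$nodes, function(g) out_degree(net, g), numeric(1))
  expect_equal(sum(degs), nrow(net$edges))
  sinks <- net$nodes[degs == 0]
  bt <- vapply(sinks[1:5], function(g) node_betweenness(net, g), numeric(1))
  expect_true(all(bt == 0))
})

test_that("global regulators are the top-k by out-degree", {
  ed <- rbind(toy_edges("w", "x1"),
              data.frame(regulator = "a", target = paste0("t", 1:9)),
              data.frame(regulator = "b", target = paste0("u", 1:7)),
              data.frame(regulator = "c", target = paste0("v", 1:5)),
              data.frame(regulator = "d", target = paste0("z", 1:3)))
  net <- build_trn(ed)
  expect_setequal(classify_global(net, 2), c("a", "b"))
  expect_error(classify_global(net, 99), "exceeds")
  # boundary tie: include all tied, with a warning
  ed2 <- rbind(ed, data.frame(regulator = "e", target = paste0("u", 1:7)))
  net2 <- build_trn(ed2)
  expect_warning(g2 <- classify_global(net2, 2), "tie")
  expect_setequal(g2, c("a", "b", "e"))
})

test_that("neighbour regulators need an immediately adjacent target", {
  genes <- sprintf("g%02d", 1:50)
  loci <- toy_loci(genes)
  ed <- toy_edges("g10", "g11",      # adjacent -> neighbour
                  "g20", "g40",      # distal only -> not neighbour
                  "g30", "g30")      # self loop only -> not neighbour
  net <- build_trn(ed)
  nb <- find_neighbour_regulators(net, loci)
  expect_equal(nb, "g10")
})

test_that("global regulators with adjacent targets are excluded", {
  genes <- sprintf("g%02d", 1:30)
  loci <- toy_loci(genes)
  ed <- rbind(toy_edges("g05", "g06"),
              data.frame(regulator = "g10", target = sprintf("g%02d", 20:29)),
              toy_edges("g10", "g11"))
  net <- build_trn(ed)
  nb <- find_neighbour_regulators(net, loci, global_set = "g10")
  expect_equal(nb, "g05")
})

test_that("adjacent heterodimer pairs regulating only each other are excluded", {
  genes <- sprintf("g%02d", 1:20)
  loci <- toy_loci(genes)
  ed <- toy_edges("g05", "g06", "g06", "g05",   # the excluded pair
                  "g10", "g11", "g11", "g10", "g11", "g12")
  net <- build_trn(ed)
  nb <- find_neighbour_regulators(net, loci)
  # g10/g11 survive: g11 also regulates a further adjacent gene
  expect_setequal(nb, c("g10", "g11"))
})

test_that("rank adjacency wraps around the circular chromosome", {
  genes <- sprintf("g%02d", 1:12)
  loci <- toy_loci(genes)
  net <- build_trn(toy_edges("g12", "g01"))
  expect_equal(find_neighbour_regulators(net, loci), "g12")
})

test_that("TFs without a locus are skipped with a warning", {
  loci <- toy_loci(sprintf("g%02d", 1:10))
  net <- build_trn(toy_edges("g02", "g03", "zz", "g05"))
  expect_warning(nb <- find_neighbour_regulators(net, loci), "zz")
  expect_equal(nb, "g02")
})

test_that("neighbourhood extraction follows the collinear run on both sides", {
  genes <- sprintf("g%02d", 1:40)
  loci <- toy_loci(genes)
  # 14 collinear targets downstream of the TF
  ed <- data.frame(regulator = "g10", target = sprintf("g%02d", 11:24))
  net <- build_trn(ed)
  nb <- extract_neighbourhood(net, loci, "g10")
  expect_equal(nb$size, 15)                       # 14 targets + the TF
  expect_equal(nb$targets, sprintf("g%02d", 11:24))
  # a single adjacent target: size-2 neighbourhood
  net2 <- build_trn(toy_edges("g30", "g31"))
  nb2 <- extract_neighbourhood(net2, loci, "g30")
  expect_equal(nb2$size, 2)
  expect_true("g30" %in% nb2$genes)
  # run truncated at the first unregulated gene
  ed3 <- toy_edges("g10", "g11", "g10", "g13", "g10", "g09")
  net3 <- build_trn(ed3)
  nb3 <- extract_neighbourhood(net3, loci, "g10")
  expect_setequal(nb3$targets, c("g09", "g11"))   # g13 cut off by gap at g12
})

test_that("global, neighbour and other partition the TF set", {
  sim <- simulate_trn(sim_config(n_tfs = 30, n_targets = 220, k_global = 5,
                                 n_neighbour = 12), seed = 4)
  cats <- classify_regulators(sim$trn, sim$loci, k = 5)
  expect_setequal(names(cats), sim$trn$tf_set)
  expect_equal(sum(cats == "global"), 5)
  expect_true(all(cats %in% c("global", "neighbour", "other")))
})
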