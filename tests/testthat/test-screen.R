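test_that("the pass rule needs two of three p-values under alpha", {
  expect_true(screen_pass(c(0.05, 0.20, 0.08)))
  expect_false(screen_pass(c(0.05, 0.20, 0.18)))
  expect_true(screen_pass(c(0.01, 0.01, 0.9)))
  expect_false(screen_pass(c(0.1, 0.1, 0.1)))   # strict <
})

test_that("fewer than 4 sequences is an error", {
  m <- rbind(a = c("A", "C"), b = c("A", "G"), c = c("A", "T"))
  expect_error(incompatibility_screen(m), "4 sequences")
})

test_that("too few informative sites fails automatically with p = 1", {
  tr <- simulate_species_tree(6, 2)
  a <- simulate_alignment(tr, 60, divergence = 0, seed = 1)  # identical seqs
  s <- incompatibility_screen(a$alignment, n_permutations = 50, seed = 1)
  expect_false(s$passed)
  expect_equal(unname(s$p_values), c(1, 1, 1))
  expect_equal(s$n_informative, 0)
})

test_that("p-values are permutation p-values in (0, 1]", {
  tr <- simulate_species_tree(10, 3)
  for (r in 1:4) {
    a <- simulate_alignment(tr, 300, divergence = 0.3, seed = 50 + r)
    s <- incompatibility_screen(a$alignment, n_permutations = 99, seed = r)
    expect_true(all(s$p_values > 0 & s$p_values <= 1))
  }
})

test_that("the screen is reproducible given a seed", {
  tr <- simulate_species_tree(9, 4)
  a <- simulate_alignment(tr, 300, divergence = 0.3, seed = 7)
  s1 <- incompatibility_screen(a$alignment, n_permutations = 200, seed = 9)
  s2 <- incompatibility_screen(a$alignment, n_permutations = 200, seed = 9)
  expect_identical(s1$p_values, s2$p_values)
})

test_that("well-separated two-segment mosaics usually pass the screen", {
  tr <- simulate_species_tree(12, 11)
  pass <- 0
  for (r in 1:15) {
    set.seed(600 + r)
    taxa <- sample(tr$tip.label, 10)
    base <- restrict_tree2(tr, taxa)
    pert <- random_spr_moves(base, 2)
    a <- simulate_alignment(list(base, pert), 600, divergence = 0.35,
                            breakpoints = 300L, seed = 700 + r)
    s <- incompatibility_screen(a$alignment, n_permutations = 200, seed = r)
    pass <- pass + s$passed
  }
  expect_gte(pass / 15, 0.8)
})

test_that("screen power is non-decreasing in divergence and length", {
  tr <- simulate_species_tree(12, 11)
  rate <- function(div, len, nrep = 12) {
    p <- 0
    for (r in 1:nrep) {
      set.seed(800 + r)
      taxa <- sample(tr$tip.label, 10)
      base <- restrict_tree2(tr, taxa)
      pert <- random_spr_moves(base, 2)
      a <- simulate_alignment(list(base, pert), len, divergence = div,
                              breakpoints = as.integer(len / 2),
                              seed = 900 + r)
      s <- incompatibility_screen(a$alignment, n_permutations = 150,
                                  seed = r)
      p <- p + s$passed
    }
    p / nrep
  }
  divs <- c(0.02, 0.2, 0.6)
  pdiv <- vapply(divs, rate, numeric(1), len = 600)
  expect_true(all(diff(pdiv) >= 0))
  lens <- c(120, 300, 600)
  plen <- vapply(lens, function(l) rate(0.35, l), numeric(1))
  expect_true(all(diff(plen) >= 0))
})
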