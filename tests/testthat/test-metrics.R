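test_that("breakpoint pairing: trivial cases and symmetry", {
  cfg <- metrics_config()
  gl <- c(g = 10000)
  a <- list(g = c(100L, 5000L, 9000L))
  d0 <- breakpoint_displacement(a, a, gl, cfg)
  expect_identical(d0$paired, 3L)
  expect_true(all(unlist(d0$displacements) == 0))
  b <- list(g = c(137L, 5037L, 9037L))
  d37 <- breakpoint_displacement(a, b, gl, cfg)
  expect_true(all(unlist(d37$displacements) == 37))
  # symmetric in its two arguments
  d73 <- breakpoint_displacement(b, a, gl, cfg)
  expect_identical(sort(unlist(d37$displacements)),
                   sort(unlist(d73$displacements)))
  expect_identical(d37$paired, d73$paired)
  # circular wrap-around distance
  dw <- breakpoint_displacement(list(g = 9990L), list(g = 5L), gl, cfg)
  expect_equal(unlist(dw$displacements), 15)
  expect_error(breakpoint_displacement(a, list(h = 1L), gl, cfg),
               "only one input")
})

test_that("optimal pairing equals the exhaustive assignment oracle", {
  cfg <- metrics_config(pairing_window = 50L)
  set.seed(61)
  for (rep in 1:25) {
    a <- sort(sample(0:500, sample(1:8, 1)))
    b <- sort(sample(0:500, sample(1:8, 1)))
    got <- breakpoint_displacement(list(g = a), list(g = b), c(g = 501),
                                   cfg, circular = FALSE, method = "optimal")
    oracle <- brute_pairing(a, b, 50L)
    expect_identical(got$paired, as.integer(oracle$npairs))
    expect_equal(sum(unlist(got$displacements)), oracle$cost)
  }
  # greedy agrees with optimal when points are well separated, the regime
  # block boundaries produce
  for (rep in 1:10) {
    a <- sort(sample(seq(0, 20000, by = 500), 10))
    b <- sort(a + sample(-40:40, 10, replace = TRUE))
    gg <- breakpoint_displacement(list(g = a), list(g = b), c(g = 20100),
                                  cfg, circular = FALSE, method = "greedy")
    go <- breakpoint_displacement(list(g = a), list(g = b), c(g = 20100),
                                  cfg, circular = FALSE, method = "optimal")
    expect_identical(gg$paired, go$paired)
    expect_equal(sum(unlist(gg$displacements)), sum(unlist(go$displacements)))
  }
})

test_that("fraction_misplaced counts threshold exceedances", {
  cfg <- metrics_config()
  expect_equal(fraction_misplaced(c(0, 0, 0), cfg), 0)
  expect_equal(fraction_misplaced(c(10, 150, 99, 101), cfg), 0.5)
  d <- tibble::tibble(genome = "g", displacements = list(c(10, 150)),
                      paired = 2L, unpaired_a = 1L, unpaired_b = 1L)
  expect_equal(fraction_misplaced(d, cfg), 0.5)
  expect_equal(fraction_misplaced(d, cfg, include_unpaired = TRUE), 0.75)
})

test_that("graph_summary matches forced outcomes and the L50/N50 oracle", {
  set.seed(62)
  s <- random_sequence(3000)
  g1 <- build_pangraph(c(a = s))
  expect_equal(graph_summary(g1)$compression, 1.0)
  # random block-length graphs vs brute-force cumulative scan
  for (rep in 1:5) {
    n_blocks <- sample(3:20, 1)
    L <- 20000
    cuts <- sort(sample(seq(100L, L - 100L, by = 100L), n_blocks - 1L))
    gg <- single_block_graph(random_sequence(L), list(list(path = "a")))
    gg <- split_block(gg, "blk1", cuts)
    sm <- graph_summary(gg)
    oracle <- brute_l50_n50(pancontig:::block_lengths(gg))
    expect_identical(sm$l50, as.integer(oracle$l50))
    expect_equal(sm$n50, oracle$n50)
    expect_lte(sm$core_length, sm$pangenome_length)
  }
})

test_that("partition_compare classifies agreement and disagreement", {
  set.seed(63)
  s1 <- random_sequence(4000)
  s2 <- mutate_sequence(s1, 30)
  pair <- c("a", "b")
  g <- build_pangraph(c(a = s1, b = s2))
  pc <- partition_compare(g, g, pair)
  expect_equal(sum(pc$fraction[pc$category == "disagree"]), 0)
  # per-genome fractions sum to 1
  sums <- tapply(pc$fraction, pc$genome, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # one graph all-shared vs one all-private -> disagreement everywhere
  g_shared <- build_pangraph(c(a = s1, b = s1))
  g_private <- union_graphs(singleton_graph("a", s1), singleton_graph("b", s1))
  pc2 <- partition_compare(g_shared, g_private, pair)
  expect_equal(sum(pc2$fraction[pc2$category == "disagree"]), 2)
})

test_that("shared k-mer estimate behaves at the extremes and corrects divergence", {
  cfg <- metrics_config()
  set.seed(64)
  s <- random_sequence(100000)
  expect_equal(shared_sequence_estimate(s, s, 0, cfg), 1.0)
  expect_lt(shared_sequence_estimate(s, random_sequence(100000), 0, cfg), 0.01)
  # 1 % mutated copy, corrected by (1-d)^k: close to 1 on average
  ests <- vapply(1:10, function(i) {
    m <- mutate_sequence(s, 1000)
    suppressWarnings(shared_sequence_estimate(s, m, 0.01, cfg))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1), 0.05)
})
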