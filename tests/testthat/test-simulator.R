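test_that("zero rates give identical genomes and empty breakpoints", {
  sp <- sim_params(n = 5L, len = 4000L, generations = 20L, mu = 0,
                   inv_rate = 0, del_rate = 0, hgt_rate = 0)
  sim <- simulate_population(sp, seed = 41L)
  expect_true(all(sim$genomes == sim$truth$ancestor))
  expect_true(all(lengths(true_breakpoints(sim$truth)) == 0L))
  # linear genomes report the origin only
  spl <- sim_params(n = 2L, len = 4000L, generations = 5L, mu = 0,
                    inv_rate = 0, del_rate = 0, hgt_rate = 0, circular = FALSE)
  siml <- simulate_population(spl, seed = 41L)
  expect_true(all(vapply(true_breakpoints(siml$truth), identical, logical(1),
                         0L)))
})

test_that("identical parameters and seed reproduce byte-identical output", {
  sp <- sim_params(n = 4L, len = 6000L, generations = 25L, mu = 3e-4)
  s1 <- simulate_population(sp, seed = 42L)
  s2 <- simulate_population(sp, seed = 42L)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_population(sp, seed = 43L)
  expect_false(identical(s1$genomes, s3$genomes))
})

test_that("substitution counts match the Poisson expectation", {
  # mu * L = 0.5 per genome per generation, T = 50 -> 25 per lineage
  counts <- unlist(lapply(1:20, function(seed) {
    sp <- sim_params(n = 10L, len = 1000L, generations = 50L, mu = 5e-4,
                     inv_rate = 0, del_rate = 0, hgt_rate = 0)
    sim <- simulate_population(sp, seed = seed)
    ev <- sim$events
    tapply(ev$type == "substitution", ev$child, sum)
  }))
  expected <- 0.5 * 50
  se <- sqrt(expected) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * (se + 1))
})

test_that("deletions shrink genomes by the expected amount", {
  lens <- unlist(lapply(1:20, function(seed) {
    sp <- sim_params(n = 5L, len = 20000L, generations = 50L, mu = 0,
                     inv_rate = 0, del_rate = 0.05, hgt_rate = 0,
                     del_mean = 500)
    nchar(simulate_population(sp, seed = 100 + seed)$genomes)
  }))
  expected <- 20000 - 0.05 * 50 * 500
  # per-genome SD ~ sqrt(E[events]) * mean length; generous 3-sigma band
  se <- sqrt(2.5) * 500 / sqrt(length(lens))
  expect_lt(abs(mean(lens) - expected), 4 * se)
})

test_that("an inversion places breakpoints exactly at its ends", {
  ind <- pancontig:::new_individual(1000L)
  ind <- pancontig:::apply_inversion(ind, 200L, 450L)
  truth <- structure(list(ancestor = random_sequence(1000),
                          individuals = list(g = ind), circular = TRUE),
                     class = "pangraph_truth")
  expect_identical(true_breakpoints(truth)$g, c(200L, 450L))
})

test_that("true breakpoints agree with an independent event-log replay", {
  sp <- sim_params(n = 5L, len = 5000L, generations = 50L, mu = 1e-4,
                   inv_rate = 0.02, del_rate = 0.05, hgt_rate = 0.1,
                   del_mean = 200, inv_mean = 500, hgt_mean = 500,
                   min_genome_length = 2000L)
  sim <- simulate_population(sp, seed = 55L)
  # replay: each genome as a vector of signed ancestor coordinates
  # (1-based magnitude, sign = orientation)
  L <- nchar(sim$truth$ancestor)
  pop <- replicate(sp$n, seq_len(L), simplify = FALSE)
  ev <- sim$events
  for (gen in seq_len(sp$generations)) {
    g_ev <- ev[ev$gen == gen, ]
    births <- g_ev[g_ev$type == "birth", ]
    newpop <- pop[births$donor[order(births$child)]]
    for (r in seq_len(nrow(g_ev))) {
      e <- g_ev[r, ]
      if (e$type %in% c("birth", "substitution")) next
      x <- newpop[[e$child]]
      idx <- (e$start + 1L):e$end
      if (e$type == "inversion") {
        x[idx] <- -rev(x[idx])
      } else if (e$type == "deletion") {
        x <- x[-idx]
      } else if (e$type == "hgt") {
        x[idx] <- pop[[e$donor]][idx]
      }
      newpop[[e$child]] <- x
    }
    pop <- newpop
  }
  replay_breakpoints <- function(x) {
    n <- length(x)
    nxt <- c(x[-1L], x[1L])
    ok <- (x > 0 & nxt == x + 1) | (x < 0 & nxt == x + 1)
    # circular wrap contiguity for the founder coordinates
    ok[x > 0 & x == L & nxt == 1] <- TRUE
    ok[x < 0 & x == -1 & nxt == -L] <- TRUE
    sort(unique(c(which(!ok) %% n)))
  }
  tb <- true_breakpoints(sim$truth)
  for (i in seq_len(sp$n)) {
    expect_identical(unname(tb[[i]]), as.integer(replay_breakpoints(pop[[i]])),
                     info = paste("genome", i))
  }
  # and the replayed coordinates reproduce the emitted sequences
  anc <- pancontig:::seq_chars(sim$truth$ancestor)
  for (i in seq_len(sp$n)) {
    base <- ifelse(pop[[i]] > 0, anc[abs(pop[[i]])],
                   pancontig:::complement_chars(anc[abs(pop[[i]])]))
    ind <- sim$truth$individuals[[i]]
    if (length(ind$sub_pos)) base[ind$sub_pos + 1L] <- ind$sub_base
    expect_identical(paste(base, collapse = ""), unname(sim$genomes[[i]]),
                     info = paste("sequence", i))
  }
})

test_that("the truth converts to a pangraph that reproduces every genome", {
  sp <- sim_params(n = 8L, len = 12000L, generations = 50L,
                   mu = mutation_rate_for_divergence(0.01, 8, 50),
                   inv_rate = 0.02, hgt_rate = 0.1)
  sim <- simulate_population(sp, seed = 56L)
  tg <- true_pangraph(sim$truth)
  validate_pangraph(tg, sim$genomes)
  tg_full <- true_pangraph(sim$truth, compact = FALSE)
  validate_pangraph(tg_full, sim$genomes)
  # without compaction, every private true breakpoint of a genome appears
  # among the true graph's boundaries (the graph refines private
  # junctions); compaction only removes junctions fixed in all genomes
  gb <- graph_breakpoints(tg_full)
  tb <- true_breakpoints(sim$truth)
  for (nm in names(tb)) {
    expect_true(all(tb[[nm]] %in% gb[[nm]]), info = nm)
  }
  expect_lte(length(tg$blocks), length(tg_full$blocks))
})
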