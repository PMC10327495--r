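test_that("pseudo-energy evaluates the merge criterion exactly", {
  p <- merge_params()
  expect_equal(pseudo_energy(0, 0, 0, p), 0)
  expect_equal(pseudo_energy(500, 2, 5, p), -250)
  # the 10 % divergence ceiling: 1000 columns with 100 polymorphisms sits
  # exactly at zero energy, i.e. not admissible
  expect_equal(pseudo_energy(1000, 0, 100, p), 0)
  expect_error(pseudo_energy(-1, 0, 0, p))
})

test_that("candidates snap cuts near block ends and count the rest", {
  set.seed(31)
  s <- random_sequence(2000)
  inner <- substr(s, 501, 1500)
  g <- union_graphs(singleton_graph("a", s, circular = FALSE),
                    singleton_graph("b", inner, circular = FALSE))
  bids <- names(g$blocks)
  full <- list(query = bids[2], ref = bids[1], strand = "+",
               qstart = 0L, qend = 1000L, rstart = 500L, rend = 1500L,
               length = 1000L, cigar = "1000=")
  cd <- candidate_from_hit(full, g, merge_params())
  expect_true(cd$valid)
  expect_identical(cd$n_c, 2L)  # two flanks on the big block
  expect_equal(cd$energy, -1000 + 200)
  # full-length on both: no cuts
  g2 <- union_graphs(singleton_graph("a", s, circular = FALSE),
                     singleton_graph("b", s, circular = FALSE))
  b2 <- names(g2$blocks)
  cd2 <- candidate_from_hit(list(query = b2[2], ref = b2[1], strand = "+",
                                 qstart = 0L, qend = 2000L, rstart = 0L,
                                 rend = 2000L, length = 2000L,
                                 cigar = "2000="), g2, merge_params())
  expect_identical(cd2$n_c, 0L)
  # a hit ending 40 bp before the end snaps: the flank is absorbed, adding
  # one terminal indel event and its length to the alignment
  cd3 <- candidate_from_hit(list(query = b2[2], ref = b2[1], strand = "+",
                                 qstart = 0L, qend = 1960L, rstart = 0L,
                                 rend = 2000L, length = 2000L,
                                 cigar = "1960=40D"), g2, merge_params())
  expect_identical(cd3$n_c, 0L)
  expect_identical(cd3$qsnap, c(0L, 2000L))
  expect_equal(cd3$len, 2040)
  # stale hit
  cd4 <- candidate_from_hit(list(query = "gone", ref = b2[1], strand = "+"),
                            g2, merge_params())
  expect_false(cd4$valid)
})

test_that("select_mergers ranks by energy and resolves conflicts greedily", {
  mk <- function(q, r, e, len) list(valid = TRUE, query = q, ref = r,
                                    energy = e, len = len)
  expect_length(select_mergers(list(mk("a", "b", 0, 500),
                                    mk("c", "d", 12, 100))), 0L)
  out <- select_mergers(list(mk("a", "b", -100, 500), mk("c", "d", -500, 900)))
  expect_identical(vapply(out, `[[`, character(1), "query"), c("c", "a"))
  # two candidates on the same block: only the lower energy survives
  out2 <- select_mergers(list(mk("a", "b", -100, 500), mk("a", "c", -500, 900)))
  expect_length(out2, 1L)
  expect_identical(out2[[1]]$ref, "c")
})

test_that("conflicting mergers are rediscovered in a later round", {
  # three identical genomes: round 1 can only merge one pair (block-level
  # conflict), the rest merges on re-alignment; end state is one block
  set.seed(32)
  s <- random_sequence(3000)
  gab <- union_graphs(singleton_graph("a", s), singleton_graph("b", s))
  gc <- singleton_graph("c", s)
  g <- pairwise_graph_merge(gab, gc, kernel_config("builtin"), merge_params())
  expect_length(g$blocks, 1L)
  expect_identical(pancontig:::block_depth(g$blocks[[1]]), 3L)
  expect_identical(unname(reconstruct_all(g)), rep(s, 3))
})

test_that("apply_merger fuses identical, SNP-bearing and reverse blocks", {
  set.seed(33)
  s <- random_sequence(1500)
  p <- merge_params()
  fuse_pair <- function(seq_b) {
    g <- union_graphs(singleton_graph("a", s, circular = FALSE),
                      singleton_graph("b", seq_b, circular = FALSE))
    hits <- align_consensus_sets(g$blocks, g$blocks, kernel_config("builtin"))
    cd <- candidate_from_hit(as.list(hits[1, ]), g, p)
    list(g = apply_merger(g, cd, p), b = seq_b)
  }
  # identical: depth 2, zero edits
  r1 <- fuse_pair(s)
  expect_length(r1$g$blocks, 1L)
  blk <- r1$g$blocks[[1]]
  expect_identical(pancontig:::block_depth(blk), 2L)
  expect_true(all(vapply(blk$nodes, pancontig:::edits_empty, logical(1))))
  # one SNP: exactly one substitution edit in the whole block
  sb <- mutate_sequence(s, n_subs = 1)
  r2 <- fuse_pair(sb)
  blk2 <- r2$g$blocks[[1]]
  expect_identical(sum(vapply(blk2$nodes, pancontig:::edits_count, integer(1))), 1L)
  expect_identical(reconstruct_sequence(r2$g, "a"), s)
  expect_identical(reconstruct_sequence(r2$g, "b"), sb)
  # reverse complement: opposite strands, both reconstruct
  r3 <- fuse_pair(revcomp(s))
  expect_length(r3$g$blocks, 1L)
  strands <- vapply(names(r3$g$blocks[[1]]$nodes),
                    function(n) r3$g$nodes[[n]]$strand, character(1))
  expect_setequal(unname(strands), c("+", "-"))
  expect_identical(reconstruct_sequence(r3$g, "a"), s)
  expect_identical(reconstruct_sequence(r3$g, "b"), revcomp(s))
})

test_that("every applied merger preserves round-trips and compresses", {
  set.seed(34)
  sp <- sim_params(n = 2L, len = 12000L, generations = 40L,
                   mu = mutation_rate_for_divergence(0.01, 2, 40))
  sim <- simulate_population(sp, seed = 35L)
  seqs <- sim$genomes
  gs <- lapply(names(seqs), function(nm) singleton_graph(nm, seqs[[nm]]))
  graph <- union_graphs(gs[[1]], gs[[2]])
  p <- merge_params()
  cfg <- kernel_config("minimap2")
  applied <- 0L
  for (round in 1:10) {
    hits <- align_consensus_sets(graph$blocks, graph$blocks, cfg)
    if (nrow(hits) == 0L) break
    cands <- lapply(seq_len(nrow(hits)), function(i) {
      candidate_from_hit(as.list(hits[i, ]), graph, p)
    })
    chosen <- select_mergers(cands)
    if (length(chosen) == 0L) break
    before <- sum(pancontig:::block_lengths(graph))
    progressed <- FALSE
    for (cd in chosen) {
      g2 <- tryCatch(apply_merger(graph, cd, p), error = function(e) NULL)
      if (is.null(g2)) next
      # invariants checked after EVERY individual merger
      expect_identical(reconstruct_all(g2)[names(seqs)], seqs)
      expect_lte(sum(pancontig:::block_lengths(g2)),
                 sum(pancontig:::block_lengths(graph)))
      graph <- g2
      applied <- applied + 1L
      progressed <- TRUE
    }
    expect_lt(sum(pancontig:::block_lengths(graph)), before)
    if (!progressed) break
  }
  expect_gte(applied, 1L)
  validate_pangraph(graph, seqs)
})

test_that("merging stops below the 10 percent divergence ceiling", {
  # ~15 % divergent pair: no admissible merger under beta = 10 with a
  # kernel that still reports the homology
  set.seed(36)
  a <- random_sequence(4000)
  b <- mutate_sequence(a, n_subs = 600)
  g <- union_graphs(singleton_graph("a", a), singleton_graph("b", b))
  hits <- align_consensus_sets(g$blocks, g$blocks, kernel_config("builtin"))
  if (nrow(hits) > 0L) {
    cands <- lapply(seq_len(nrow(hits)), function(i) {
      candidate_from_hit(as.list(hits[i, ]), g, merge_params())
    })
    expect_length(select_mergers(cands), 0L)
  }
  gm <- pairwise_graph_merge(singleton_graph("a", a), singleton_graph("b", b),
                             kernel_config("builtin"), merge_params())
  expect_length(gm$blocks, 2L)
})

test_that("build_pangraph handles the degenerate and forced cases", {
  set.seed(37)
  s <- random_sequence(5000)
  g1 <- build_pangraph(c(solo = s))
  expect_length(g1$blocks, 1L)
  expect_identical(path_names(g1), "solo")
  # merged graphs are a fixed point: no admissible candidate remains
  seqs <- c(a = s, b = mutate_sequence(s, 20))
  g <- build_pangraph(seqs)
  hits <- align_consensus_sets(g$blocks, g$blocks, kernel_config())
  cands <- lapply(seq_len(nrow(hits)), function(i) {
    candidate_from_hit(as.list(hits[i, ]), g, merge_params())
  })
  expect_length(select_mergers(cands), 0L)
  expect_error(build_pangraph(c(s, s)), "unique")
  expect_error(build_pangraph(c(a = "", b = s)), "empty")
})
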