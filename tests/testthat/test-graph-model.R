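test_that("reconstruction applies edits, strands and rotation", {
  cons <- "ACGTACGTAC"
  # identity case
  g <- single_block_graph(cons, list(list(path = "a")))
  expect_identical(reconstruct_sequence(g, "a"), cons)
  # one substitution at position 3 (0-based)
  g2 <- single_block_graph(cons, list(
    list(path = "a",
         edits = pancontig:::make_edits(sub_pos = 3L, sub_base = "G"))))
  expect_identical(reconstruct_sequence(g2, "a"), "ACGGACGTAC")
  # reverse strand occurrence
  g3 <- single_block_graph(cons, list(list(path = "a", strand = "-")))
  expect_identical(reconstruct_sequence(g3, "a"), revcomp(cons))
  # unknown path errors
  expect_error(reconstruct_sequence(g, "nope"), "unknown path")
})

test_that("edit application handles insertions, deletions and boundaries", {
  me <- pancontig:::make_edits
  ap <- pancontig:::apply_edits
  expect_identical(ap("AAAAAA", me(ins_pos = 0L, ins_seq = "TT")), "TTAAAAAA")
  expect_identical(ap("AAAAAA", me(ins_pos = 6L, ins_seq = "GG")), "AAAAAAGG")
  expect_identical(ap("AAAAAA", me(del_pos = 2L, del_len = 2L)), "AAAA")
  expect_identical(
    ap("ACGTAC", me(sub_pos = 0L, sub_base = "T", ins_pos = 3L,
                    ins_seq = "GG", del_pos = 4L, del_len = 1L)),
    "TCGGGTC")
  # flip is an involution and matches reverse-complemented application
  ed <- me(sub_pos = 1L, sub_base = "T", ins_pos = 4L, ins_seq = "CA",
           del_pos = 2L, del_len = 2L)
  cons <- "ACGTACGG"
  fl <- pancontig:::flip_edits(ed, nchar(cons))
  expect_identical(pancontig:::flip_edits(fl, nchar(cons)), ed)
  expect_identical(ap(revcomp(cons), fl), revcomp(ap(cons, ed)))
})

test_that("recompute_consensus votes columns and preserves members", {
  me <- pancontig:::make_edits
  # depth-1 block: consensus becomes the member sequence, edits empty
  g <- single_block_graph("ACGTACGTAC", list(
    list(path = "a", edits = me(sub_pos = 2L, sub_base = "T",
                                del_pos = 5L, del_len = 2L,
                                ins_pos = 8L, ins_seq = "AA"))))
  before <- reconstruct_sequence(g, "a")
  b2 <- recompute_consensus(g$blocks[[1]])
  expect_identical(b2$consensus, before)
  expect_true(all(vapply(b2$nodes, pancontig:::edits_empty, logical(1))))

  # 3 x 10 toy alignment: 2 of 3 members share A->G at column 4; the vote
  # moves the consensus to G and leaves one substitution on the minority
  cons <- "ACGTACGTAC"
  occs <- list(
    list(path = "x", edits = me(sub_pos = 4L, sub_base = "G")),
    list(path = "y", edits = me(sub_pos = 4L, sub_base = "G")),
    list(path = "z"))
  g3 <- single_block_graph(cons, occs)
  seqs_before <- sort(reconstruct_all(g3))
  b3 <- recompute_consensus(g3$blocks[[1]])
  expect_identical(substr(b3$consensus, 5, 5), "G")
  ed_z <- b3$nodes[["z:1"]]
  expect_identical(ed_z$sub_pos, 4L)
  expect_identical(ed_z$sub_base, "A")
  g3$blocks[[1]] <- b3
  expect_identical(sort(reconstruct_all(g3)), seqs_before)
})

test_that("split_block partitions edits and reverses sub-block order on -", {
  set.seed(5)
  s <- random_sequence(300)
  g <- single_block_graph(s, list(list(path = "f"), list(path = "r", strand = "-")))
  expect_identical(split_block(g, "blk1", integer(0)), g)
  g2 <- split_block(g, "blk1", c(120L, 200L))
  expect_length(g2$blocks, 3L)
  expect_identical(reconstruct_sequence(g2, "f"), s)
  expect_identical(reconstruct_sequence(g2, "r"), revcomp(s))
  # reverse path visits sub-blocks in swapped order, all reverse
  rsteps <- g2$paths[["r"]]$nodes
  rlens <- vapply(rsteps, function(n) {
    nchar(g2$blocks[[g2$nodes[[n]]$block]]$consensus)
  }, numeric(1))
  expect_identical(unname(rlens), c(100, 80, 120))
  expect_true(all(vapply(rsteps, function(n) g2$nodes[[n]]$strand, character(1)) == "-"))
  expect_error(split_block(g, "blk1", 300L), "cut outside")
  expect_error(split_block(g, "blk1", c(10L, 10L)), "duplicate")
  # an indel spanning a cut is split at the cut
  ged <- single_block_graph("ACGTACGTAC", list(
    list(path = "a", edits = pancontig:::make_edits(del_pos = 3L, del_len = 4L))))
  before <- reconstruct_sequence(ged, "a")
  gs <- split_block(ged, "blk1", 5L)
  expect_identical(reconstruct_sequence(gs, "a"), before)
  dels <- lapply(gs$blocks, function(b) b$nodes[[1]]$del_pos)
  expect_true(all(lengths(dels) == 1L))
})

test_that("flip_block is an involution and conserves reconstruction", {
  set.seed(6)
  s <- random_sequence(200)
  g <- single_block_graph(s, list(
    list(path = "a", edits = pancontig:::make_edits(sub_pos = 10L, sub_base = "N")),
    list(path = "b", strand = "-")))
  gf <- flip_block(g, "blk1")
  expect_identical(reconstruct_sequence(gf, "a"), reconstruct_sequence(g, "a"))
  expect_identical(reconstruct_sequence(gf, "b"), reconstruct_sequence(g, "b"))
  expect_identical(flip_block(gf, "blk1"), g)
})

test_that("polish reduces duplicated indels and conserves members", {
  me <- pancontig:::make_edits
  # identical members: polishing changes nothing
  g0 <- single_block_graph("ACGTACGTACGTACGTACGT",
                           list(list(path = "a"), list(path = "b")))
  expect_identical(polish_block(g0$blocks[[1]]), g0$blocks[[1]])
  # both members carry the same 5 bp insertion (a merge artefact shape):
  # the vote should absorb it into the consensus, shrinking total edits
  set.seed(8)
  cons <- random_sequence(400)
  ins <- "TTGCA"
  occs <- list(
    list(path = "a", edits = me(ins_pos = 200L, ins_seq = ins)),
    list(path = "b", edits = me(ins_pos = 200L, ins_seq = ins)),
    list(path = "c", edits = me(ins_pos = 200L, ins_seq = ins,
                                sub_pos = 50L, sub_base = "N")))
  g <- single_block_graph(cons, occs)
  seqs <- reconstruct_all(g)
  before <- sum(vapply(g$blocks[[1]]$nodes, pancontig:::edits_count, integer(1)))
  pb <- polish_block(g$blocks[[1]])
  after <- sum(vapply(pb$nodes, pancontig:::edits_count, integer(1)))
  expect_lte(after, before)
  g$blocks[[1]] <- pb
  expect_identical(reconstruct_all(g), seqs)
})

test_that("validate_pangraph catches broken cross-references", {
  g <- single_block_graph("ACGTACGT", list(list(path = "a")))
  expect_true(validate_pangraph(g, c(a = "ACGTACGT")))
  bad <- g
  bad$paths[["a"]]$nodes <- c(bad$paths[["a"]]$nodes, "ghost")
  expect_error(validate_pangraph(bad))
})
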