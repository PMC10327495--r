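# Core data structures: pancontigs (blocks), paths, and whole pangraphs.
#
# Internal representation:
#   graph$blocks : named list, id -> list(id, consensus, nodes = list(nid -> edits))
#   graph$nodes  : named list, nid -> list(block, path, strand)   (strand "+"/"-")
#   graph$paths  : named list, name -> list(name, nodes = chr vector, circular, offset)
#
# A "node" is one visit of one genome to one block; paths are ordered node-id
# vectors, so path steps and block occurrences stay in bijection by
# construction.  All consensus coordinates are 0-based half-open.

new_pangraph <- function(blocks = list(), nodes = list(), paths = list()) {
  structure(list(blocks = blocks, nodes = nodes, paths = paths),
            class = "pangraph")
}

#' Build a trivial single-block graph from one genome
#'
#' @param name Genome identifier.
#' @param seq Nucleotide sequence.
#' @param circular Is the genome circular?
#' @return A `pangraph` with one pancontig and one path.
#' @export
singleton_graph <- function(name, seq, circular = TRUE) {
  stopifnot(nzchar(seq))
  bid <- hash_id("blk", name)
  nid <- paste0(name, ":1")
  blocks <- list()
  blocks[[bid]] <- list(id = bid, consensus = toupper(seq),
                        nodes = stats::setNames(list(empty_edits()), nid))
  nodes <- stats::setNames(list(list(block = bid, path = name, strand = "+")), nid)
  paths <- stats::setNames(
    list(list(name = name, nodes = nid, circular = circular, offset = 0L)),
    name)
  new_pangraph(blocks, nodes, paths)
}

#' @export
print.pangraph <- function(x, ...) {
  np <- length(x$paths)
  nb <- length(x$blocks)
  tot <- sum(vapply(x$blocks, function(b) nchar(b$consensus), numeric(1)))
  cat(sprintf("<pangraph> %d pancontig(s), %d path(s), %s bp consensus\n",
              nb, np, format(tot, big.mark = ",")))
  invisible(x)
}

block_depth <- function(block) length(block$nodes)

block_lengths <- function(graph) {
  vapply(graph$blocks, function(b) nchar(b$consensus), numeric(1))
}

#' Genome names present in a graph
#' @param graph A `pangraph`.
#' @return Character vector of path names.
#' @export
path_names <- function(graph) names(graph$paths)

# Segment of one node (occurrence) in path orientation.
node_segment <- function(graph, nid) {
  nd <- graph$nodes[[nid]]
  if (is.null(nd)) stop("unknown node id: ", nid)
  blk <- graph$blocks[[nd$block]]
  seg <- apply_edits(blk$consensus, blk$nodes[[nid]])
  if (nd$strand == "-") seg <- revcomp(seg) else seg
}

#' Reconstruct a genome sequence from its path
#'
#' Concatenates, in step order, each visited block's consensus with that
#' occurrence's edits applied, reverse-complemented for reverse-strand
#' steps; circular paths are rotated by the stored start offset.
#'
#' @param graph A `pangraph`.
#' @param name Genome (path) identifier.
#' @return The reconstructed nucleotide string.
#' @export
reconstruct_sequence <- function(graph, name) {
  p <- graph$paths[[name]]
  if (is.null(p)) stop("unknown path name: ", name)
  segs <- vapply(p$nodes, function(nid) node_segment(graph, nid), character(1))
  s <- paste(segs, collapse = "")
  off <- p$offset %||% 0L
  if (off > 0L) s <- paste0(substr(s, off + 1L, nchar(s)), substr(s, 1L, off))
  s
}

#' Reconstruct every genome in a graph
#' @param graph A `pangraph`.
#' @return Named character vector of sequences.
#' @export
reconstruct_all <- function(graph) {
  vapply(graph$paths, function(p) reconstruct_sequence(graph, p$name),
         character(1))
}

# --- structural validation -------------------------------------------------

#' Validate the internal consistency of a pangraph
#'
#' Checks the occurrence/step bijection, edit validity against each
#' consensus, and (optionally) exact round-trip reconstruction against
#' reference sequences.
#'
#' @param graph A `pangraph`.
#' @param reference Optional named character vector of genome sequences to
#'   compare reconstructions against.
#' @return `TRUE` invisibly; errors on any violation.
#' @export
validate_pangraph <- function(graph, reference = NULL) {
  nids_paths <- unlist(lapply(graph$paths, `[[`, "nodes"), use.names = FALSE)
  if (anyDuplicated(nids_paths)) stop("node id appears twice in paths")
  if (!setequal(nids_paths, names(graph$nodes)))
    stop("path steps and node registry disagree")
  nids_blocks <- unlist(lapply(graph$blocks, function(b) names(b$nodes)),
                        use.names = FALSE)
  if (!setequal(nids_blocks, names(graph$nodes)))
    stop("block occurrences and node registry disagree")
  for (b in graph$blocks) {
    if (!nzchar(b$consensus)) stop("empty consensus in block ", b$id)
    if (length(b$nodes) < 1L) stop("block ", b$id, " has no occurrences")
    L <- nchar(b$consensus)
    for (nid in names(b$nodes)) {
      validate_edits(b$nodes[[nid]], L)
      nd <- graph$nodes[[nid]]
      if (is.null(nd) || nd$block != b$id)
        stop("node ", nid, " not registered to block ", b$id)
    }
  }
  for (p in graph$paths) {
    for (nid in p$nodes) {
      if (graph$nodes[[nid]]$path != p$name)
        stop("node ", nid, " not registered to path ", p$name)
    }
  }
  if (!is.null(reference)) {
    for (nm in names(reference)) {
      if (!identical(reconstruct_sequence(graph, nm), toupper(reference[[nm]])))
        stop("round-trip reconstruction failed for ", nm)
    }
  }
  invisible(TRUE)
}

# --- block alignment matrix ------------------------------------------------

# Build the full implied alignment of a block: a members x columns character
# matrix including padded insertion columns, plus the pattern of consensus
# columns.  Insertions from different members at the same slot are
# left-anchored and padded with gaps.
block_alignment_matrix <- function(block) {
  L <- nchar(block$consensus)
  cons <- seq_chars(block$consensus)
  nids <- names(block$nodes)
  d <- length(nids)
  widths <- integer(L + 1L)
  for (ed in block$nodes) {
    if (length(ed$ins_pos)) {
      w <- nchar(ed$ins_seq)
      slot <- ed$ins_pos + 1L
      widths[slot] <- pmax(widths[slot], w)
    }
  }
  nc <- L + sum(widths)
  # column index (1-based) of consensus position p (0-based):
  cumw <- cumsum(widths)         # cumw[p+1] = total insertion width in slots <= p
  cons_col <- seq_len(L) + cumw[seq_len(L)]
  slot_start <- c(0L, seq_len(L) + cumw[seq_len(L)])  # col before slot content
  pattern <- rep("-", nc)
  pattern[cons_col] <- cons
  mat <- matrix("-", nrow = d, ncol = nc, dimnames = list(nids, NULL))
  for (i in seq_len(d)) {
    ed <- block$nodes[[i]]
    mat[i, cons_col] <- base_row_chars(cons, ed)
    if (length(ed$ins_pos)) {
      for (j in seq_along(ed$ins_pos)) {
        s <- ed$ins_seq[j]
        st <- slot_start[ed$ins_pos[j] + 1L]
        mat[i, st + seq_len(nchar(s))] <- seq_chars(s)
      }
    }
  }
  list(mat = mat, pattern = pattern, cons_col = cons_col)
}

#' Recompute a block's consensus by column-wise majority vote
#'
#' The implied multiple alignment (consensus columns plus insertion
#' columns) is voted column by column; all occurrences' edits are
#' re-expressed against the winning consensus.  Reconstructed member
#' sequences are unchanged.
#'
#' @param block A pancontig (as stored in `graph$blocks`).
#' @return The updated block.
#' @export
recompute_consensus <- function(block) {
  al <- block_alignment_matrix(block)
  pat <- vote_columns(al$mat)
  new_cons <- paste(pat[pat != "-"], collapse = "")
  if (!nzchar(new_cons)) {
    # degenerate: majority voted everything away; keep the old consensus
    return(block)
  }
  nodes <- lapply(seq_len(nrow(al$mat)), function(i) {
    edits_from_row(pat, al$mat[i, ])
  })
  names(nodes) <- rownames(al$mat)
  block$consensus <- new_cons
  block$nodes <- nodes
  block
}

recompute_consensus_in_graph <- function(graph, block_id) {
  graph$blocks[[block_id]] <- recompute_consensus(graph$blocks[[block_id]])
  graph
}

# --- block splitting -------------------------------------------------------

#' Split a pancontig at consensus offsets
#'
#' The block is replaced by sub-blocks in consensus order; every path that
#' visited it now visits the sub-blocks consecutively (in reverse order for
#' reverse-strand occurrences); edits are partitioned, with indels spanning
#' a cut split at the cut.  Round-trip reconstruction is unchanged.
#'
#' @param graph A `pangraph`.
#' @param block_id Block to split.
#' @param cuts Sorted distinct offsets strictly inside `(0, L)`.
#' @return The updated graph.  With empty `cuts`, the graph is returned
#'   unchanged.
#' @export
split_block <- function(graph, block_id, cuts) {
  blk <- graph$blocks[[block_id]]
  if (is.null(blk)) stop("unknown block id: ", block_id)
  cuts <- as.integer(cuts)
  if (length(cuts) == 0L) return(graph)
  L <- nchar(blk$consensus)
  if (any(cuts <= 0L | cuts >= L)) stop("cut outside (0, L)")
  if (anyDuplicated(cuts)) stop("duplicate cuts")
  cuts <- sort(cuts)
  bounds <- c(0L, cuts, L)
  k <- length(bounds) - 1L
  sub_ids <- vapply(seq_len(k), function(i) hash_id("split", block_id, i),
                    character(1))
  while (anyDuplicated(c(names(graph$blocks), sub_ids))) {
    sub_ids <- paste0(sub_ids, "x")  # deterministic collision escape
  }
  sub_cons <- substring(blk$consensus, bounds[-length(bounds)] + 1L, bounds[-1L])
  new_blocks <- lapply(seq_len(k), function(i) {
    list(id = sub_ids[i], consensus = sub_cons[i], nodes = list())
  })
  names(new_blocks) <- sub_ids
  # partition each occurrence
  for (nid in names(blk$nodes)) {
    parts <- split_edits(blk$nodes[[nid]], cuts, L)
    nd <- graph$nodes[[nid]]
    sub_nids <- paste0(nid, ".", seq_len(k))
    for (i in seq_len(k)) {
      new_blocks[[i]]$nodes[[sub_nids[i]]] <- parts[[i]]
      graph$nodes[[sub_nids[i]]] <- list(block = sub_ids[i], path = nd$path,
                                         strand = nd$strand)
    }
    # path step replacement: forward keeps consensus order, reverse flips it
    p <- graph$paths[[nd$path]]
    at <- match(nid, p$nodes)
    repl <- if (nd$strand == "+") sub_nids else rev(sub_nids)
    p$nodes <- append(p$nodes[-at], repl, after = at - 1L)
    graph$paths[[nd$path]] <- p
    graph$nodes[[nid]] <- NULL
  }
  graph$blocks[[block_id]] <- NULL
  graph$blocks <- c(graph$blocks, new_blocks)
  graph
}

# --- orientation flip ------------------------------------------------------

#' Flip a block's orientation convention
#'
#' Reverse-complements the consensus, re-expresses all edits in the flipped
#' frame and toggles every occurrence's strand.  Reconstruction is
#' unchanged; applying the flip twice restores the graph exactly.
#'
#' @param graph A `pangraph`.
#' @param block_id Block to flip.
#' @return The updated graph.
#' @export
flip_block <- function(graph, block_id) {
  blk <- graph$blocks[[block_id]]
  if (is.null(blk)) stop("unknown block id: ", block_id)
  L <- nchar(blk$consensus)
  blk$consensus <- revcomp(blk$consensus)
  blk$nodes <- lapply(blk$nodes, flip_edits, L = L)
  graph$blocks[[block_id]] <- blk
  for (nid in names(blk$nodes)) {
    graph$nodes[[nid]]$strand <- if (graph$nodes[[nid]]$strand == "+") "-" else "+"
  }
  graph
}

# --- polishing -------------------------------------------------------------

#' Re-align the members of a block
#'
#' Performs a star realignment: each member sequence is re-aligned globally
#' against the consensus with an affine-gap pairwise aligner, edits are
#' re-derived from the fresh alignments, and the consensus is recomputed by
#' majority vote (absorbing indels shared by a majority of members).
#' Member sequences are unchanged; merge artefacts such as double-counted
#' indels are removed or reduced.
#'
#' @param block A pancontig with depth >= 2.
#' @param rounds Realignment/vote iterations (default 2).
#' @return The polished block.
#' @export
polish_block <- function(block, rounds = 2L) {
  stopifnot(block_depth(block) >= 2L)
  members <- vapply(names(block$nodes), function(nid) {
    apply_edits(block$consensus, block$nodes[[nid]])
  }, character(1))
  for (r in seq_len(rounds)) {
    before <- sum(vapply(block$nodes, edits_count, integer(1)))
    nodes <- lapply(members, function(m) align_member_to_consensus(m, block$consensus))
    names(nodes) <- names(block$nodes)
    cand <- block
    cand$nodes <- nodes
    cand <- recompute_consensus(cand)
    after <- sum(vapply(cand$nodes, edits_count, integer(1)))
    if (after > before) break  # never accept a worse encoding
    block <- cand
    if (after == before) break
  }
  block
}

# Global pairwise alignment of a member against the consensus, returned as
# an edit list.  Small sequences only (quadratic DP).
align_member_to_consensus <- function(member, consensus) {
  if (identical(member, consensus)) return(empty_edits())
  aln <- Biostrings::pairwiseAlignment(
    pattern = member, subject = consensus, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 0.5)
  prow <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  srow <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  edits_from_row(srow, prow)
}

#' Polish every block of depth >= 2 in a graph
#' @param graph A `pangraph`.
#' @param rounds Iterations passed to [polish_block()].
#' @return The polished graph.
#' @export
polish_pangraph <- function(graph, rounds = 2L) {
  for (bid in names(graph$blocks)) {
    if (block_depth(graph$blocks[[bid]]) >= 2L) {
      graph$blocks[[bid]] <- polish_block(graph$blocks[[bid]], rounds = rounds)
    }
  }
  graph
}

# --- broom-style methods ---------------------------------------------------

#' Tidy block table of a pangraph
#'
#' @param x A `pangraph`.
#' @param ... Unused.
#' @return A tibble with one row per pancontig: id, consensus length,
#'   depth, number of distinct genomes, and core status (present exactly
#'   once in every genome).
#' @export
tidy.pangraph <- function(x, ...) {
  n_genomes <- length(x$paths)
  rows <- purrr::map(x$blocks, function(b) {
    paths <- vapply(names(b$nodes), function(nid) x$nodes[[nid]]$path, character(1))
    tibble::tibble(
      block = b$id,
      length = nchar(b$consensus),
      depth = length(b$nodes),
      n_genomes = length(unique(paths)),
      core = length(paths) == n_genomes && length(unique(paths)) == n_genomes
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$length))
}

#' One-row summary of a pangraph
#'
#' @param x A `pangraph`.
#' @param ... Unused.
#' @return The [graph_summary()] tibble.
#' @export
glance.pangraph <- function(x, ...) graph_summary(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
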