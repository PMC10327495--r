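# Pseudo-energy ranked merging of homologous pancontig intervals.
#
# A merger candidate joins an interval of a query block with an interval of
# a reference block along an alignment.  Its pseudo-energy is
#     E = -l + alpha * N_c + beta * N_m
# where l is the alignment length, N_c the number of additional blocks the
# merger creates (cuts not at block ends), and N_m the polymorphism count of
# the consensus-consensus alignment.  Only E < 0 mergers are performed; the
# loop re-aligns and repeats until no admissible merger remains.

#' Merge parameters
#'
#' @param alpha Block-creation cost in bp-equivalents (default 100).
#' @param beta Polymorphism cost in bp-equivalents (default 10); no merger
#'   is admissible once consensus divergence exceeds `1/beta`.
#' @param len_min Minimal pancontig length in bp (default 100); cut points
#'   closer than this to a block end snap to the end and the alignment is
#'   extended over the absorbed flank.
#' @param max_rounds Safety cap on align/merge rounds (default 64).
#' @return A `merge_params` list.
#' @export
merge_params <- function(alpha = 100, beta = 10, len_min = 100L,
                         max_rounds = 64L) {
  stopifnot(alpha >= 0, beta >= 0, len_min >= 0)
  structure(list(alpha = alpha, beta = beta, len_min = as.integer(len_min),
                 max_rounds = as.integer(max_rounds)),
            class = "merge_params")
}

#' Pseudo-energy of a candidate merger
#'
#' @param len Alignment length in bp (columns).
#' @param n_c Number of additional pancontigs the merger creates (0..4).
#' @param n_m Polymorphism count of the consensus-consensus alignment.
#' @param params A [merge_params()].
#' @return The energy in bp-equivalents; the merger is admissible iff the
#'   value is negative.
#' @export
pseudo_energy <- function(len, n_c, n_m, params = merge_params()) {
  stopifnot(all(len >= 0), all(n_c >= 0), all(n_m >= 0))
  -len + params$alpha * n_c + params$beta * n_m
}

snap_interval <- function(s, e, L, len_min) {
  if (s < len_min) s <- 0L
  if (L - e < len_min) e <- L
  c(s, e)
}

#' Build a merge candidate from a hit
#'
#' Cut points within `len_min` of a block end snap to the end (the
#' alignment is extended across the absorbed flank, which enters as a
#' terminal indel); `N_c` counts the remaining cuts; `N_m` adds one event
#' per absorbed flank to the cigar's polymorphism count.
#'
#' @param hit One row of a hit tibble.
#' @param graph The `pangraph` providing block lengths.
#' @param params A [merge_params()].
#' @return A list candidate (`valid = FALSE` when the hit is stale or
#'   degenerate).
#' @export
candidate_from_hit <- function(hit, graph, params = merge_params()) {
  qb <- graph$blocks[[hit$query]]
  rb <- graph$blocks[[hit$ref]]
  if (is.null(qb) || is.null(rb)) {
    return(list(valid = FALSE, reason = "stale"))
  }
  Lq <- nchar(qb$consensus); Lr <- nchar(rb$consensus)
  qi <- snap_interval(hit$qstart, hit$qend, Lq, params$len_min)
  ri <- snap_interval(hit$rstart, hit$rend, Lr, params$len_min)
  if (hit$query == hit$ref) {
    if (hit$strand == "-") {
      return(list(valid = FALSE, reason = "self-inverted"))
    }
    if (qi[1] < ri[2] && ri[1] < qi[2]) {
      return(list(valid = FALSE, reason = "overlapping self intervals"))
    }
    # the stretch between the two intervals becomes its own block: refuse
    # mergers that would emit one shorter than len_min
    gap <- if (qi[2] <= ri[1]) ri[1] - qi[2] else qi[1] - ri[2]
    if (gap > 0L && gap < params$len_min) {
      return(list(valid = FALSE, reason = "sub-minimal tandem gap"))
    }
  }
  n_c <- sum(qi[1] > 0L, qi[2] < Lq, ri[1] > 0L, ri[2] < Lr)
  flanks <- c(hit$qstart - qi[1], qi[2] - hit$qend,
              hit$rstart - ri[1], ri[2] - hit$rend)
  len <- hit$length + sum(flanks)
  n_m <- cigar_polymorphisms(hit$cigar) + sum(flanks > 0L)
  list(valid = TRUE,
       query = hit$query, ref = hit$ref, strand = hit$strand,
       qstart = hit$qstart, qend = hit$qend,
       rstart = hit$rstart, rend = hit$rend,
       qsnap = qi, rsnap = ri, cigar = hit$cigar,
       len = len, n_c = n_c, n_m = n_m,
       energy = pseudo_energy(len, n_c, n_m, params))
}

#' Select the admissible mergers for one round
#'
#' Keeps candidates with negative energy, sorted ascending by energy (ties:
#' longer alignment first, then lexicographic block-id pair), and resolves
#' conflicts greedily: once a block is consumed by a selected merger, later
#' candidates touching it are dropped for this round (they are rediscovered
#' by the next round's re-alignment).
#'
#' @param candidates List of candidates from [candidate_from_hit()].
#' @return Ordered list of selected candidates.
#' @export
select_mergers <- function(candidates) {
  keep <- purrr::keep(candidates, function(cd) isTRUE(cd$valid) && cd$energy < 0)
  if (length(keep) == 0L) return(list())
  ord <- order(vapply(keep, `[[`, numeric(1), "energy"),
               -vapply(keep, `[[`, numeric(1), "len"),
               vapply(keep, function(cd) paste(cd$query, cd$ref), character(1)))
  keep <- keep[ord]
  locked <- character(0)
  out <- list()
  for (cd in keep) {
    if (cd$query %in% locked || cd$ref %in% locked) next
    out[[length(out) + 1L]] <- cd
    locked <- c(locked, cd$query, cd$ref)
  }
  out
}

# split a block and report the sub-block ids in consensus order
split_block_ids <- function(graph, block_id, cuts) {
  if (length(cuts) == 0L) {
    return(list(graph = graph, ids = block_id,
                bounds = c(0L, nchar(graph$blocks[[block_id]]$consensus))))
  }
  L <- nchar(graph$blocks[[block_id]]$consensus)
  k <- length(cuts) + 1L
  ids <- vapply(seq_len(k), function(i) hash_id("split", block_id, i), character(1))
  while (anyDuplicated(c(names(graph$blocks), ids))) ids <- paste0(ids, "x")
  g2 <- split_block(graph, block_id, cuts)
  list(graph = g2, ids = ids, bounds = c(0L, sort(as.integer(cuts)), L))
}

#' Apply one merger to a graph
#'
#' Both blocks are split at the snapped hit boundaries, the homologous
#' sub-blocks are fused along the (extended) alignment, edits are lifted
#' through the map, the consensus is recomputed by majority vote, and all
#' path steps are rewired.  Round-trip reconstruction is preserved for
#' every genome.  On a cigar/coordinate inconsistency the merger errors
#' without touching the graph.
#'
#' @param graph A `pangraph`.
#' @param cand An admissible candidate from [candidate_from_hit()].
#' @param params A [merge_params()].
#' @return The updated graph.
#' @export
apply_merger <- function(graph, cand, params = merge_params()) {
  stopifnot(isTRUE(cand$valid))
  qb <- graph$blocks[[cand$query]]
  rb <- graph$blocks[[cand$ref]]
  if (is.null(qb) || is.null(rb)) stop("stale candidate: block consumed")
  Lq <- nchar(qb$consensus); Lr <- nchar(rb$consensus)
  # verify the cigar is consistent before mutating anything
  ops <- parse_cigar(cand$cigar)
  sp <- cigar_span(ops)
  if (sp$query != cand$qend - cand$qstart || sp$ref != cand$rend - cand$rstart)
    stop("cigar span inconsistent with hit intervals")

  qs <- cand$qstart; qe <- cand$qend
  if (cand$strand == "-") {
    graph <- flip_block(graph, cand$query)
    qs <- Lq - cand$qend
    qe <- Lq - cand$qstart
  }
  qi <- snap_interval(qs, qe, Lq, params$len_min)
  ri <- snap_interval(cand$rstart, cand$rend, Lr, params$len_min)
  # extend the cigar across absorbed flanks (terminal indels)
  pre <- list(len = c(qs - qi[1], cand$rstart - ri[1]), op = c("I", "D"))
  post <- list(len = c(qi[2] - qe, ri[2] - cand$rend), op = c("I", "D"))
  ops <- list(len = c(pre$len, ops$len, post$len),
              op = c(pre$op, ops$op, post$op))
  cigar <- cigar_string(ops)

  if (cand$query == cand$ref) {
    cuts <- setdiff(sort(unique(c(qi, ri))), c(0L, Lq))
    sq <- split_block_ids(graph, cand$query, cuts)
    graph <- sq$graph
    qmid <- sq$ids[findInterval(qi[1], sq$bounds) ]
    rmid <- sq$ids[findInterval(ri[1], sq$bounds) ]
  } else {
    sq <- split_block_ids(graph, cand$query, setdiff(qi, c(0L, Lq)))
    graph <- sq$graph
    qmid <- sq$ids[findInterval(qi[1], sq$bounds)]
    sr <- split_block_ids(graph, cand$ref, setdiff(ri, c(0L, Lr)))
    graph <- sr$graph
    rmid <- sr$ids[findInterval(ri[1], sr$bounds)]
  }
  fuse_blocks(graph, rmid, qmid, cigar)
}

# Fuse a query sub-block onto a reference sub-block along a cigar whose
# query/ref spans equal the two consensus lengths.  Node ids survive, so
# paths need no rewiring.
fuse_blocks <- function(graph, rbid, qbid, cigar) {
  tb <- graph$blocks[[rbid]]
  qb <- graph$blocks[[qbid]]
  ops <- parse_cigar(cigar)
  sp <- cigar_span(ops)
  if (sp$ref != nchar(tb$consensus) || sp$query != nchar(qb$consensus))
    stop("cigar does not span the fused blocks")
  opv <- rep(ops$op, ops$len)
  ncig <- length(opv)
  t_has <- opv != "I"
  q_has <- opv != "D"
  tcol <- which(t_has)   # cigar column of each target consensus position
  qcol <- which(q_has)
  Lt <- nchar(tb$consensus); Lq2 <- nchar(qb$consensus)

  # insertion slots: key k in 1..ncig+1 means "before cigar column k"
  key_t <- function(p) if (p < Lt) tcol[p + 1L] else ncig + 1L
  key_q <- function(p) if (p < Lq2) qcol[p + 1L] else ncig + 1L
  widths <- integer(ncig + 1L)
  note_ins <- function(keys, lens) {
    for (i in seq_along(keys)) widths[keys[i]] <<- max(widths[keys[i]], lens[i])
  }
  tkeys <- lapply(tb$nodes, function(ed) vapply(ed$ins_pos, key_t, integer(1)))
  qkeys <- lapply(qb$nodes, function(ed) vapply(ed$ins_pos, key_q, integer(1)))
  for (i in seq_along(tb$nodes)) note_ins(tkeys[[i]], nchar(tb$nodes[[i]]$ins_seq))
  for (i in seq_along(qb$nodes)) note_ins(qkeys[[i]], nchar(qb$nodes[[i]]$ins_seq))

  nctot <- ncig + sum(widths)
  cumw <- cumsum(widths)  # cumw[k] = slot width at keys <= k
  basecol <- seq_len(ncig) + cumw[seq_len(ncig)]  # final index of cigar column j
  slot_first <- function(k) (k - 1L) + if (k > 1L) cumw[k - 1L] else 0L  # cols before slot k

  tcons <- seq_chars(tb$consensus)
  qcons <- seq_chars(qb$consensus)
  nT <- length(tb$nodes); nQ <- length(qb$nodes)
  nids <- c(names(tb$nodes), names(qb$nodes))
  mat <- matrix("-", nrow = nT + nQ, ncol = nctot, dimnames = list(nids, NULL))
  fill_member <- function(row_i, cons, ed, colmap, keys) {
    r <- base_row_chars(cons, ed)
    mat[row_i, basecol[colmap]] <<- r
    if (length(ed$ins_pos)) {
      for (j in seq_along(ed$ins_pos)) {
        s <- ed$ins_seq[j]
        st <- slot_first(keys[j])
        mat[row_i, st + seq_len(nchar(s))] <<- seq_chars(s)
      }
    }
  }
  for (i in seq_len(nT)) fill_member(i, tcons, tb$nodes[[i]], tcol, tkeys[[i]])
  for (i in seq_len(nQ)) fill_member(nT + i, qcons, qb$nodes[[i]], qcol, qkeys[[i]])

  pat <- vote_columns(mat)
  new_cons <- paste(pat[pat != "-"], collapse = "")
  if (!nzchar(new_cons)) stop("fusion produced an empty consensus")
  nodes <- lapply(seq_len(nrow(mat)), function(i) edits_from_row(pat, mat[i, ]))
  names(nodes) <- nids

  fid <- hash_id("fuse", rbid, qbid)
  while (fid %in% setdiff(names(graph$blocks), c(rbid, qbid))) fid <- paste0(fid, "x")
  graph$blocks[[rbid]] <- NULL
  graph$blocks[[qbid]] <- NULL
  graph$blocks[[fid]] <- list(id = fid, consensus = new_cons, nodes = nodes)
  for (nid in nids) graph$nodes[[nid]]$block <- fid
  graph
}

# --- pairwise graph merge --------------------------------------------------

#' Align and merge two pangraphs
#'
#' Forms the union graph, then loops: all-to-all consensus alignment of
#' the union (self-alignment included, so duplications can merge), build
#' and rank candidates, apply the admissible ones, and repeat until no
#' negative-energy merger remains.  Transitive chains are compacted at the
#' end.  Deterministic for fixed inputs.
#'
#' @param graphA,graphB `pangraph`s with disjoint path-name sets.
#' @param cfg A [kernel_config()].
#' @param params A [merge_params()].
#' @return The merged `pangraph`.
#' @export
pairwise_graph_merge <- function(graphA, graphB, cfg = kernel_config(),
                                 params = merge_params()) {
  if (length(intersect(path_names(graphA), path_names(graphB))))
    stop("path name sets must be disjoint")
  if (length(intersect(names(graphA$blocks), names(graphB$blocks))))
    stop("internal block-id collision between graphs")
  graph <- new_pangraph(c(graphA$blocks, graphB$blocks),
                        c(graphA$nodes, graphB$nodes),
                        c(graphA$paths, graphB$paths))
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > params$max_rounds) {
      warning("merge loop hit the round cap (", params$max_rounds,
              ") before reaching a fixed point")
      break
    }
    hits <- align_consensus_sets(graph$blocks, graph$blocks, cfg)
    if (nrow(hits) == 0L) break
    cands <- lapply(seq_len(nrow(hits)), function(i) {
      candidate_from_hit(as.list(hits[i, ]), graph, params)
    })
    chosen <- select_mergers(cands)
    if (length(chosen) == 0L) break
    applied <- 0L
    for (cd in chosen) {
      g2 <- tryCatch(apply_merger(graph, cd, params), error = function(e) NULL)
      if (!is.null(g2)) { graph <- g2; applied <- applied + 1L }
    }
    if (applied == 0L) break
  }
  merge_transitive(graph)
}

# --- full progressive build ------------------------------------------------

#' Build a pangenome graph from a set of genomes
#'
#' Starts from one single-pancontig graph per genome and merges pairwise
#' along the balanced guide tree's post-order schedule.
#'
#' @param seqs Named character vector of genome sequences (or a path to a
#'   FASTA file).
#' @param circular Are the genomes circular? (Default `TRUE`.)
#' @param sketch A [sketch_params()] for the guide tree.
#' @param cfg A [kernel_config()].
#' @param params A [merge_params()].
#' @param job_order Optional permutation of schedule rows to execute
#'   (must be topologically valid); used to demonstrate schedule
#'   independence.  Default: post-order.
#' @return The final `pangraph`, with the guide tree and parameters
#'   attached as attributes `guide_tree` and `build_params`.
#' @export
build_pangraph <- function(seqs, circular = TRUE, sketch = sketch_params(),
                           cfg = kernel_config(), params = merge_params(),
                           job_order = NULL) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_fasta(seqs)
  nms <- names(seqs)
  if (is.null(nms) || anyDuplicated(nms)) stop("genome names must be unique")
  if (any(!nzchar(seqs))) stop("empty genome sequence")
  graphs <- lapply(nms, function(nm) singleton_graph(nm, seqs[[nm]], circular))
  names(graphs) <- nms
  if (length(graphs) == 1L) {
    g <- graphs[[1]]
  } else {
    tree <- build_guide_tree(seqs, sketch)
    sched <- merge_schedule(tree)
    ord <- job_order %||% seq_len(nrow(sched))
    stopifnot(setequal(ord, seq_len(nrow(sched))))
    done <- graphs
    for (i in ord) {
      row <- sched[i, ]
      gl <- done[[row$left]]
      gr <- done[[row$right]]
      if (is.null(gl) || is.null(gr))
        stop("job order is not topologically valid: ", row$job)
      done[[row$job]] <- pairwise_graph_merge(gl, gr, cfg, params)
      done[[row$left]] <- NULL
      done[[row$right]] <- NULL
    }
    g <- done[[sched$job[nrow(sched)]]]
    attr(g, "guide_tree") <- tree
  }
  attr(g, "build_params") <- list(sketch = sketch, kernel = cfg, merge = params)
  g
}
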