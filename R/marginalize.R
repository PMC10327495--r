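# Projection of a pangraph onto a strain subset, without re-alignment.

#' Merge transitive pancontig chains
#'
#' Fuses every pair of blocks that are adjacent with identical relative
#' orientation in all occurrences (and have equal depth), repeatedly until
#' a fixed point.  Round-trip reconstruction is preserved.  A circular
#' path consisting of a single block is left untouched.
#'
#' @param graph A `pangraph`.
#' @return The compacted graph.
#' @export
merge_transitive <- function(graph) {
  repeat {
    fused <- FALSE
    edges <- collect_block_adjacencies(graph)
    if (nrow(edges) == 0L) return(graph)
    depth <- vapply(graph$blocks, block_depth, integer(1))
    tab <- dplyr::count(edges, .data$x, .data$sx, .data$y, .data$sy)
    tab <- tab[tab$x != tab$y, , drop = FALSE]
    tab <- tab[tab$n == depth[tab$x] & tab$n == depth[tab$y], , drop = FALSE]
    if (nrow(tab) == 0L) return(graph)
    tab <- dplyr::arrange(tab, .data$x, .data$y, .data$sx, .data$sy)
    locked <- character(0)
    for (i in seq_len(nrow(tab))) {
      e <- tab[i, ]
      if (e$x %in% locked || e$y %in% locked) next
      graph <- fuse_chain(graph, e$x, e$sx, e$y, e$sy)
      locked <- c(locked, e$x, e$y)
      fused <- TRUE
    }
    if (!fused) return(graph)
  }
}

# An adjacency between consecutive path steps (a then b) can be written two
# ways: (a.block, a.strand) -> (b.block, b.strand), or its mirror
# (b.block, !b.strand) -> (a.block, !a.strand).  We keep the
# lexicographically smaller representation so identical adjacencies seen
# from either genome direction coincide.
collect_block_adjacencies <- function(graph) {
  rows <- list()
  for (p in graph$paths) {
    n <- length(p$nodes)
    if (n < 2L) next
    nxt <- c(seq_len(n)[-1L], if (p$circular) 1L else NA_integer_)
    for (i in seq_len(n)) {
      j <- nxt[i]
      if (is.na(j)) next
      a <- graph$nodes[[p$nodes[i]]]
      b <- graph$nodes[[p$nodes[j]]]
      k1 <- paste(a$block, a$strand, b$block, b$strand)
      k2 <- paste(b$block, flip_strand(b$strand), a$block, flip_strand(a$strand))
      rows[[length(rows) + 1L]] <- if (k1 <= k2) {
        list(x = a$block, sx = a$strand, y = b$block, sy = b$strand)
      } else {
        list(x = b$block, sx = flip_strand(b$strand),
             y = a$block, sy = flip_strand(a$strand))
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(x = character(0), sx = character(0),
                          y = character(0), sy = character(0)))
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

orient_edits <- function(ed, strand, L) {
  if (strand == "-") flip_edits(ed, L) else ed
}

# Fuse the chain (X, sx) -> (Y, sy): every occurrence of X is adjacent to
# the same oriented Y.  The fused consensus is orient(X, sx) ++
# orient(Y, sy); occurrences matching the canonical direction become
# forward nodes, mirrored ones reverse.
fuse_chain <- function(graph, x, sx, y, sy) {
  xb <- graph$blocks[[x]]
  yb <- graph$blocks[[y]]
  Lx <- nchar(xb$consensus)
  Ly <- nchar(yb$consensus)
  xcons <- if (sx == "-") revcomp(xb$consensus) else xb$consensus
  ycons <- if (sy == "-") revcomp(yb$consensus) else yb$consensus
  zid <- hash_id("chain", x, sx, y, sy)
  while (zid %in% names(graph$blocks)) zid <- paste0(zid, "x")
  znodes <- list()
  zstrand <- character(0)
  for (nx in names(xb$nodes)) {
    nd <- graph$nodes[[nx]]
    p <- graph$paths[[nd$path]]
    at <- match(nx, p$nodes)
    n <- length(p$nodes)
    canonical <- nd$strand == sx
    j <- if (canonical) {
      if (at < n) at + 1L else if (p$circular) 1L else NA_integer_
    } else {
      if (at > 1L) at - 1L else if (p$circular) n else NA_integer_
    }
    if (is.na(j)) stop("internal: chain partner missing for node ", nx)
    ny <- p$nodes[j]
    ndy <- graph$nodes[[ny]]
    expected <- if (canonical) sy else flip_strand(sy)
    if (ndy$block != y || ndy$strand != expected)
      stop("internal: inconsistent chain partner for node ", nx)
    edx <- orient_edits(xb$nodes[[nx]], sx, Lx)
    edy <- orient_edits(yb$nodes[[ny]], sy, Ly)
    znodes[[nx]] <- concat_edits(edx, edy, Lx)
    zstrand[nx] <- if (canonical) "+" else "-"
    # fusing across the circular wrap junction rotates the concatenation;
    # compensate in the path's start offset so reconstruction is unchanged
    wrap <- p$circular &&
      ((canonical && at == n && j == 1L) || (!canonical && at == 1L && j == n))
    if (wrap) {
      seg_lens <- vapply(p$nodes, function(id) nchar(node_segment(graph, id)),
                         numeric(1))
      Lg <- sum(seg_lens)
      ly <- seg_lens[[j]]
      off <- p$offset %||% 0L
      p$offset <- as.integer((if (canonical) off - ly else off + ly) %% Lg)
    }
    p$nodes <- p$nodes[-j]
    graph$paths[[nd$path]] <- p
    graph$nodes[[ny]] <- NULL
  }
  for (nx in names(znodes)) {
    graph$nodes[[nx]]$block <- zid
    graph$nodes[[nx]]$strand <- zstrand[[nx]]
  }
  graph$blocks[[x]] <- NULL
  graph$blocks[[y]] <- NULL
  graph$blocks[[zid]] <- list(id = zid, consensus = paste0(xcons, ycons),
                              nodes = znodes)
  graph
}

#' Project a pangraph onto a subset of genomes
#'
#' Paths outside `keep` are removed, their occurrences pruned, depth-0
#' blocks deleted, consensuses recomputed from the remaining members, and
#' transitive chains merged.  No re-alignment is performed; reconstruction
#' stays exact for every kept genome.
#'
#' @param graph A `pangraph`.
#' @param keep Character vector of genome names to retain (non-empty
#'   subset of `path_names(graph)`).
#' @return The marginalized `pangraph`.
#' @export
marginalize <- function(graph, keep) {
  stopifnot(length(keep) >= 1L)
  unknown <- setdiff(keep, path_names(graph))
  if (length(unknown)) stop("unknown genome name(s): ", paste(unknown, collapse = ", "))
  drop <- setdiff(path_names(graph), keep)
  touched <- character(0)
  for (nm in drop) {
    p <- graph$paths[[nm]]
    for (nid in p$nodes) {
      bid <- graph$nodes[[nid]]$block
      b <- graph$blocks[[bid]]
      b$nodes[[nid]] <- NULL
      graph$blocks[[bid]] <- b
      graph$nodes[[nid]] <- NULL
      touched <- c(touched, bid)
    }
    graph$paths[[nm]] <- NULL
  }
  for (bid in unique(touched)) {
    if (length(graph$blocks[[bid]]$nodes) == 0L) {
      graph$blocks[[bid]] <- NULL
    } else {
      graph$blocks[[bid]] <- recompute_consensus(graph$blocks[[bid]])
    }
  }
  merge_transitive(graph)
}
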