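# Independent oracles and small fixture builders shared across tests.

# --- brute-force minimizer oracle: O(L * w) scan, window minimum at every
# offset, collecting every hash that attains its window's minimum
brute_minimizer_hashes <- function(seq, k, w) {
  codes <- pancontig:::canonical_kmer_codes(seq, k)
  h <- pancontig:::hash32(codes)
  n <- length(h) - w + 1L
  out <- numeric(0)
  for (i in seq_len(n)) {
    win <- h[i:(i + w - 1L)]
    if (anyNA(win)) next
    out <- c(out, win[win == min(win)])
  }
  sort(unique(out))
}

# --- naive per-pair Jaccard from sketch hash sets
naive_jaccard <- function(sk1, sk2) {
  a <- sk1$hash; b <- sk2$hash
  1 - length(intersect(a, b)) / length(union(a, b))
}

# --- four-point condition oracle for a 4-taxon additive matrix: returns the
# split partner of taxon 1 under the best of the 3 unrooted topologies
four_point_partner <- function(D) {
  stopifnot(nrow(D) == 4)
  sums <- c(D[1, 2] + D[3, 4],   # 12|34
            D[1, 3] + D[2, 4],   # 13|24
            D[1, 4] + D[2, 3])   # 14|23
  c(2L, 3L, 4L)[which.min(sums)]
}

# --- brute-force L50/N50 from a length vector
brute_l50_n50 <- function(lens) {
  s <- sort(unname(lens), decreasing = TRUE)
  tot <- sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc > tot / 2) return(list(l50 = i, n50 = s[i]))
  }
}

# --- exhaustive max-cardinality min-cost matching of two small point sets
# within a window (recursion over the first list)
brute_pairing <- function(a, b, window, L = NULL, circular = FALSE) {
  dist1 <- function(x, y) {
    d <- abs(x - y)
    if (circular) min(d, L - d) else d
  }
  best <- list(npairs = -1, cost = Inf)
  recurse <- function(i, used_b, npairs, cost) {
    if (i > length(a)) {
      if (npairs > best$npairs ||
          (npairs == best$npairs && cost < best$cost)) {
        best <<- list(npairs = npairs, cost = cost)
      }
      return(invisible())
    }
    recurse(i + 1L, used_b, npairs, cost)  # leave a[i] unpaired
    for (j in seq_along(b)) {
      if (used_b[j]) next
      d <- dist1(a[i], b[j])
      if (d <= window) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, npairs + 1L, cost + d)
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(b)), 0L, 0)
  best
}

# --- manual graph builders ------------------------------------------------

# One block, several occurrences; each occurrence becomes its own
# single-step path.  occs: list of list(path=, strand=, edits=).
single_block_graph <- function(consensus, occs, circular = FALSE) {
  bid <- "blk1"
  nodes <- list(); paths <- list(); bn <- list()
  for (oc in occs) {
    nid <- paste0(oc$path, ":1")
    bn[[nid]] <- oc$edits %||% pancontig:::empty_edits()
    nodes[[nid]] <- list(block = bid, path = oc$path,
                         strand = oc$strand %||% "+")
    paths[[oc$path]] <- list(name = oc$path, nodes = nid,
                             circular = circular, offset = 0L)
  }
  pancontig:::new_pangraph(
    blocks = stats::setNames(
      list(list(id = bid, consensus = consensus, nodes = bn)), bid),
    nodes = nodes, paths = paths)
}

# One path walking the given oriented blocks; blocks: named list of
# consensus strings; steps: list of list(block=, strand=, edits=).
walk_graph <- function(blocks, steps, path_name = "g1", circular = FALSE) {
  nodes <- list()
  bdefs <- lapply(names(blocks), function(b) list(id = b, consensus = blocks[[b]],
                                                  nodes = list()))
  names(bdefs) <- names(blocks)
  nids <- character(0)
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    nid <- paste0(path_name, ":", i)
    nids <- c(nids, nid)
    bdefs[[st$block]]$nodes[[nid]] <- st$edits %||% pancontig:::empty_edits()
    nodes[[nid]] <- list(block = st$block, path = path_name,
                         strand = st$strand %||% "+")
  }
  pancontig:::new_pangraph(
    blocks = bdefs, nodes = nodes,
    paths = stats::setNames(
      list(list(name = path_name, nodes = nids, circular = circular,
                offset = 0L)), path_name))
}

union_graphs <- function(...) {
  gs <- list(...)
  pancontig:::new_pangraph(
    blocks = do.call(c, lapply(gs, `[[`, "blocks")),
    nodes = do.call(c, lapply(gs, `[[`, "nodes")),
    paths = do.call(c, lapply(gs, `[[`, "paths")))
}

mutate_sequence <- function(seq, n_subs = 0L, seed = NULL) {
  v <- pancontig:::seq_chars(seq)
  if (n_subs > 0L) {
    pos <- sample(length(v), n_subs)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}
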