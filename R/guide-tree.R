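# Guide tree: minimizer sketches -> Jaccard distances -> neighbour joining
# -> balanced binary tree -> post-order merge schedule.

#' Minimizer sketch parameters
#' @param k K-mer length in bp (1..26).
#' @param w Window size in bp (>= 1); the minimum-hash k-mer of every
#'   window of `w` consecutive k-mers is retained.
#' @return A `sketch_params` list.
#' @export
sketch_params <- function(k = 15L, w = 10L) {
  stopifnot(k >= 1L, k <= 26L, w >= 1L)
  structure(list(k = as.integer(k), w = as.integer(w)), class = "sketch_params")
}

#' Minimizer sketch of a sequence
#'
#' Canonical (strand-symmetric) k-mers are hashed with an invertible
#' 32-bit multiplicative hash; each window of `w` consecutive k-mers
#' contributes its minimum-hash k-mer.  The sketch of a sequence equals
#' the sketch of its reverse complement.
#'
#' @param seq Nucleotide string (or character vector of contigs; the
#'   sketch is the union over contigs).
#' @param params A [sketch_params()] object.
#' @param kmers Also decode the canonical k-mer strings? (Slower; off by
#'   default.)
#' @return A tibble with columns `hash` (and `kmer` if requested), one
#'   row per distinct minimizer.
#' @export
minimizer_sketch <- function(seq, params = sketch_params(), kmers = FALSE) {
  k <- params$k; w <- params$w
  hashes <- numeric(0)
  kept_codes <- numeric(0)
  for (s in seq) {
    if (nchar(s) < k + w - 1L) {
      stop("sequence shorter than one window (need >= k + w - 1 = ",
           k + w - 1L, " bp)")
    }
    codes <- canonical_kmer_codes(s, k)
    h <- hash32(codes)
    n <- length(h) - w + 1L
    wmin <- h[seq_len(n)]
    if (w > 1L) {
      for (j in 1L:(w - 1L)) wmin <- pmin(wmin, h[seq_len(n) + j], na.rm = FALSE)
    }
    # a k-mer is a minimizer if it attains the minimum of any window
    keep <- logical(length(h))
    for (j in 0L:(w - 1L)) {
      idx <- seq_len(n) + j
      keep[idx] <- keep[idx] | (!is.na(h[idx]) & !is.na(wmin) & h[idx] == wmin)
    }
    hashes <- c(hashes, h[keep])
    kept_codes <- c(kept_codes, codes[keep])
  }
  ok <- !is.na(hashes)
  hashes <- hashes[ok]; kept_codes <- kept_codes[ok]
  first <- !duplicated(hashes)
  o <- order(hashes[first])
  out <- tibble::tibble(hash = hashes[first][o])
  if (kmers) out$kmer <- decode_kmer(kept_codes[first][o], k)
  out
}

#' Jaccard distance matrix from minimizer sketches
#'
#' `D[i, j] = 1 - |S_i \U{2229} S_j| / |S_i \U{222A} S_j|`.  Intersection
#' cardinalities are computed from one global ordering of all minimizers
#' (a sparse incidence cross-product), not nested per-pair scans.
#'
#' @param sketches List of sketch tibbles from [minimizer_sketch()].
#' @param labels Optional names for rows/columns.
#' @return Symmetric numeric matrix with zero diagonal, values in \[0, 1\].
#' @export
jaccard_distance_matrix <- function(sketches, labels = NULL) {
  n <- length(sketches)
  stopifnot(n >= 2L)
  sizes <- vapply(sketches, nrow, integer(1))
  if (any(sizes == 0L)) stop("empty sketch")
  all_h <- unlist(lapply(sketches, `[[`, "hash"), use.names = FALSE)
  gidx <- rep(seq_len(n), sizes)
  # global sort of all minimizers: factor levels are the sorted uniques
  f <- match(all_h, sort(unique(all_h)))
  A <- Matrix::sparseMatrix(i = f, j = gidx, x = 1,
                            dims = c(max(f), n))
  I <- as.matrix(Matrix::crossprod(A))
  U <- outer(sizes, sizes, "+") - I
  D <- 1 - I / U
  diag(D) <- 0
  dimnames(D) <- list(labels, labels)
  D
}

# --- guide tree structure --------------------------------------------------
# A guide tree node is either list(leaf = <name>) or list(left=, right=).

new_leaf <- function(label) list(leaf = label)
is_leaf <- function(node) !is.null(node$leaf)

tree_leaves <- function(node) {
  if (is_leaf(node)) return(node$leaf)
  c(tree_leaves(node$left), tree_leaves(node$right))
}

tree_depth <- function(node) {
  if (is_leaf(node)) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' Neighbour-joining guide tree
#'
#' Classical neighbour joining on a symmetric distance matrix, returned as
#' a rooted strictly binary topology (rooted at the final agglomeration).
#' Only the left-to-right leaf ordering matters downstream, where the tree
#' is rebalanced by [balance_guide_tree()].
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param labels Leaf labels (defaults to `rownames(D)`).
#' @return A guide tree (nested list; leaves carry `$leaf`).
#' @export
neighbor_joining_tree <- function(D, labels = rownames(D)) {
  n <- nrow(D)
  stopifnot(n >= 2L, ncol(D) == n, length(labels) == n)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-9)) || any(diag(D) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  if (n == 2L) return(list(left = new_leaf(labels[1]), right = new_leaf(labels[2])))
  dimnames(D) <- list(labels, labels)
  phy <- tryCatch(ape::nj(stats::as.dist(D)),
                  error = function(e) NULL)
  if (is.null(phy)) {
    # degenerate matrices (e.g. all-zero distances): fall back to input order
    return(balanced_from_order(labels))
  }
  phy <- ape::reorder.phylo(phy, "cladewise")
  tips <- phy$edge[, 2][phy$edge[, 2] <= length(phy$tip.label)]
  ord <- phy$tip.label[tips]
  # rebuild a rooted binary topology preserving the NJ leaf ordering by
  # successively joining along the cladewise order of the unrooted tree
  caterpillar_from_order(ord)
}

caterpillar_from_order <- function(ord) {
  node <- new_leaf(ord[1])
  for (l in ord[-1]) node <- list(left = node, right = new_leaf(l))
  node
}

balanced_from_order <- function(ord) {
  n <- length(ord)
  if (n == 1L) return(new_leaf(ord[1]))
  h <- ceiling(n / 2)
  list(left = balanced_from_order(ord[seq_len(h)]),
       right = balanced_from_order(ord[(h + 1L):n]))
}

#' Balance a guide tree, preserving leaf order
#'
#' Rebuilds the tree by recursive halving of the left-to-right leaf
#' sequence: output depth is `ceiling(log2(n))` and the leaf order equals
#' the input tree's leaf order.
#'
#' @param tree A guide tree.
#' @return A balanced guide tree.
#' @export
balance_guide_tree <- function(tree) {
  balanced_from_order(tree_leaves(tree))
}

#' Post-order merge schedule of a guide tree
#'
#' Each internal node is one pairwise graph-merge job.  Jobs in disjoint
#' subtrees are independent and may execute in any order; the merged graph
#' is identical regardless.
#'
#' @param tree A (balanced) guide tree.
#' @return A tibble with columns `job`, `left`, `right`, `leaves`.
#'   `left`/`right` name either a leaf (genome) or a prior job id of the
#'   form `"job:<i>"`; `leaves` is a list-column of the subtree's genomes.
#' @export
merge_schedule <- function(tree) {
  jobs <- list()
  walk <- function(node) {
    if (is_leaf(node)) return(node$leaf)
    l <- walk(node$left)
    r <- walk(node$right)
    id <- paste0("job:", length(jobs) + 1L)
    jobs[[length(jobs) + 1L]] <<- tibble::tibble(
      job = id, left = l, right = r,
      leaves = list(tree_leaves(node)))
    id
  }
  walk(tree)
  if (length(jobs) == 0L) {
    return(tibble::tibble(job = character(0), left = character(0),
                          right = character(0), leaves = list()))
  }
  dplyr::bind_rows(jobs)
}

#' Newick export of a guide tree
#' @param tree A guide tree.
#' @return A Newick string (topology only, no branch lengths).
#' @export
guide_tree_newick <- function(tree) {
  render <- function(node) {
    if (is_leaf(node)) return(node$leaf)
    paste0("(", render(node$left), ",", render(node$right), ")")
  }
  paste0(render(tree), ";")
}

#' Build the balanced guide tree for a set of genomes
#'
#' Sketch, Jaccard distances, neighbour joining, then balancing.  With a
#' single genome the tree is a lone leaf; with two, a cherry.
#'
#' @param seqs Named character vector (or named list of character vectors
#'   for multi-contig genomes).
#' @param params [sketch_params()].
#' @return A balanced guide tree.
#' @export
build_guide_tree <- function(seqs, params = sketch_params()) {
  nms <- names(seqs)
  stopifnot(!is.null(nms), !anyDuplicated(nms))
  if (length(seqs) == 1L) return(new_leaf(nms[1]))
  sketches <- lapply(seqs, minimizer_sketch, params = params)
  D <- jaccard_distance_matrix(sketches, labels = nms)
  balance_guide_tree(neighbor_joining_tree(D, nms))
}
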