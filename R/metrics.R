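# Quantitative evaluation: breakpoint displacement, graph summaries,
# partition agreement between graphs, divergence-corrected shared k-mers.

#' Metrics configuration
#'
#' @param pairing_window Breakpoints further apart than this are never
#'   paired (default 1000 bp).
#' @param displacement_threshold A paired breakpoint displaced by more
#'   than this counts as misplaced (default 100 bp, the minimal pancontig
#'   length).
#' @param kmer K for the shared-k-mer estimate (default 21).
#' @return A `metrics_config` list.
#' @export
metrics_config <- function(pairing_window = 1000L,
                           displacement_threshold = 100L, kmer = 21L) {
  stopifnot(pairing_window > 0L, displacement_threshold > 0L, kmer > 0L)
  structure(list(pairing_window = as.integer(pairing_window),
                 displacement_threshold = as.integer(displacement_threshold),
                 kmer = as.integer(kmer)),
            class = "metrics_config")
}

#' Block boundaries of each genome in a graph
#'
#' Positions (0-based, extant-genome coordinates) where consecutive path
#' steps meet.  For circular paths the wrap junction is reported at the
#' rotation origin when the path has more than one step.
#'
#' @param graph A `pangraph`.
#' @return Named list of sorted integer positions per genome.
#' @export
graph_breakpoints <- function(graph) {
  out <- lapply(graph$paths, function(p) {
    n <- length(p$nodes)
    if (n == 0L) return(integer(0))
    lens <- vapply(p$nodes, function(nid) nchar(node_segment(graph, nid)),
                   numeric(1))
    cum <- cumsum(lens)
    L <- cum[n]
    bp <- if (n > 1L) as.integer(cum[-n]) else integer(0)
    if (p$circular) {
      if (n > 1L) bp <- c(0L, bp)
    } else {
      bp <- c(0L, bp)
    }
    off <- p$offset %||% 0L
    if (off > 0L) bp <- sort(unique((bp - off) %% L))
    sort(unique(bp))
  })
  out
}

circ_dist <- function(a, b, L, circular) {
  d <- abs(a - b)
  if (circular) pmin(d, L - d) else d
}

# greedy closest-first pairing within a window; each point used once
pair_greedy <- function(a, b, window, L, circular) {
  if (length(a) == 0L || length(b) == 0L)
    return(tibble::tibble(a = integer(0), b = integer(0), d = numeric(0)))
  cand <- expand.grid(i = seq_along(a), j = seq_along(b))
  cand$d <- circ_dist(a[cand$i], b[cand$j], L, circular)
  cand <- cand[cand$d <= window, , drop = FALSE]
  cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
  used_i <- logical(length(a)); used_j <- logical(length(b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_i[i] && !used_j[j]) {
      keep[r] <- TRUE; used_i[i] <- TRUE; used_j[j] <- TRUE
    }
  }
  sel <- cand[keep, , drop = FALSE]
  tibble::tibble(a = a[sel$i], b = b[sel$j], d = sel$d)
}

# maximum-cardinality, minimum-cost non-crossing assignment of two sorted
# 1-D point sets (linear coordinates); dynamic programme over (i, j)
pair_optimal <- function(a, b, window, L, circular) {
  a <- sort(a); b <- sort(b)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L)
    return(tibble::tibble(a = integer(0), b = integer(0), d = numeric(0)))
  big <- (sum(abs(a)) + sum(abs(b)) + window + 1) * (n + m + 1)
  # score = pairs * big - cost, maximized
  S <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- max(S[i, j + 1L], S[i + 1L, j])
      d <- circ_dist(a[i], b[j], L, circular)
      if (d <= window) best <- max(best, S[i, j] + big - d)
      S[i + 1L, j + 1L] <- best
    }
  }
  # traceback
  pa <- integer(0); pb <- integer(0); pd <- numeric(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    d <- circ_dist(a[i], b[j], L, circular)
    if (d <= window && S[i + 1L, j + 1L] == S[i, j] + big - d) {
      pa <- c(a[i], pa); pb <- c(b[j], pb); pd <- c(d, pd)
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1L, j + 1L] == S[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  tibble::tibble(a = pa, b = pb, d = pd)
}

#' Pair breakpoints of two graphs and measure displacements
#'
#' Breakpoints of the same genome in the two inputs are paired within the
#' configured window (greedy nearest-neighbour by default, or a
#' max-cardinality min-cost assignment with `method = "optimal"`);
#' displacement is the (circular, where applicable) distance between
#' partners.  Unpaired breakpoints are counted separately.
#'
#' @param bp_a,bp_b Named lists of sorted positions per genome (e.g. from
#'   [graph_breakpoints()] and [true_breakpoints()]).
#' @param genome_lengths Named numeric vector of genome lengths (needed
#'   for circular distances).
#' @param cfg A [metrics_config()].
#' @param circular Use circular distances? (Default `TRUE`.)
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A tibble with one row per genome: list-column `displacements`,
#'   and counts `paired`, `unpaired_a`, `unpaired_b`.
#' @export
breakpoint_displacement <- function(bp_a, bp_b, genome_lengths,
                                    cfg = metrics_config(), circular = TRUE,
                                    method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (!setequal(names(bp_a), names(bp_b)))
    stop("genome present in only one input: ",
         paste(union(setdiff(names(bp_a), names(bp_b)),
                     setdiff(names(bp_b), names(bp_a))), collapse = ", "))
  rows <- lapply(names(bp_a), function(nm) {
    a <- bp_a[[nm]]; b <- bp_b[[nm]]
    L <- genome_lengths[[nm]]
    pairs <- if (method == "greedy") {
      pair_greedy(a, b, cfg$pairing_window, L, circular)
    } else {
      pair_optimal(a, b, cfg$pairing_window, L, circular)
    }
    tibble::tibble(genome = nm, displacements = list(pairs$d),
                   paired = nrow(pairs),
                   unpaired_a = length(a) - nrow(pairs),
                   unpaired_b = length(b) - nrow(pairs))
  })
  dplyr::bind_rows(rows)
}

#' Fraction of paired breakpoints misplaced beyond the threshold
#'
#' @param displacement A tibble from [breakpoint_displacement()], or a
#'   bare numeric vector of displacements.
#' @param cfg A [metrics_config()].
#' @param include_unpaired Count unpaired breakpoints as misplaced?
#'   (Default `FALSE`: they are excluded and reported separately.)
#' @return A single fraction in \[0, 1\] (`NaN` when nothing is paired).
#' @export
fraction_misplaced <- function(displacement, cfg = metrics_config(),
                               include_unpaired = FALSE) {
  if (is.numeric(displacement)) {
    d <- displacement
    n_un <- 0L
  } else {
    d <- unlist(displacement$displacements, use.names = FALSE)
    n_un <- sum(displacement$unpaired_a) + sum(displacement$unpaired_b)
  }
  bad <- sum(d > cfg$displacement_threshold)
  if (include_unpaired) (bad + n_un) / (length(d) + n_un)
  else bad / length(d)
}

#' Summary statistics of a pangraph
#'
#' @param graph A `pangraph`.
#' @return One-row tibble: `n_genomes`, `n_blocks`, `pangenome_length`
#'   (sum of consensus lengths), `total_genome_length`, `compression`
#'   (pangenome length / total genome length), `core_blocks`,
#'   `core_length`, `core_fraction` (core length / pangenome length),
#'   `l50` (minimum number of blocks covering half the pangenome), `n50`
#'   (length of the shortest block in that set).
#' @export
graph_summary <- function(graph) {
  lens <- block_lengths(graph)
  n_gen <- length(graph$paths)
  pang <- sum(lens)
  glen <- sum(vapply(path_names(graph), function(nm) {
    nchar(reconstruct_sequence(graph, nm))
  }, numeric(1)))
  core <- vapply(graph$blocks, function(b) {
    paths <- vapply(names(b$nodes), function(nid) graph$nodes[[nid]]$path,
                    character(1))
    length(paths) == n_gen && length(unique(paths)) == n_gen
  }, logical(1))
  slen <- sort(lens, decreasing = TRUE)
  cum <- cumsum(slen)
  l50 <- which(cum > pang / 2)[1]
  tibble::tibble(
    n_genomes = n_gen,
    n_blocks = length(lens),
    pangenome_length = pang,
    total_genome_length = glen,
    compression = pang / glen,
    core_blocks = sum(core),
    core_length = sum(lens[core]),
    core_fraction = sum(lens[core]) / pang,
    l50 = as.integer(l50),
    n50 = as.numeric(slen[l50]))
}

# shared/private interval partition of each genome in a two-genome graph
partition_intervals <- function(graph, pair) {
  stopifnot(setequal(path_names(graph), pair))
  lapply(stats::setNames(pair, pair), function(nm) {
    p <- graph$paths[[nm]]
    other <- setdiff(pair, nm)
    lens <- vapply(p$nodes, function(nid) nchar(node_segment(graph, nid)),
                   numeric(1))
    shared <- vapply(p$nodes, function(nid) {
      b <- graph$blocks[[graph$nodes[[nid]]$block]]
      paths <- vapply(names(b$nodes), function(x) graph$nodes[[x]]$path,
                      character(1))
      other %in% paths
    }, logical(1))
    ends <- cumsum(lens)
    tibble::tibble(start = c(0, ends[-length(ends)]), end = ends,
                   shared = shared)
  })
}

rotate_labels <- function(lab, off) {
  if (off == 0L) return(lab)
  c(lab[(off + 1L):length(lab)], lab[seq_len(off)])
}

label_positions <- function(iv, L) {
  # label per unit interval: TRUE = shared
  lab <- logical(L)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i])
      lab[(iv$start[i] + 1):iv$end[i]] <- iv$shared[i]
  }
  lab
}

segment_runs <- function(cat, circular) {
  r <- rle(cat)
  lens <- r$lengths
  vals <- r$values
  if (circular && length(vals) > 1L && vals[1] == vals[length(vals)]) {
    lens[1] <- lens[1] + lens[length(lens)]
    lens <- lens[-length(lens)]
    vals <- vals[-length(vals)]
  }
  tibble::tibble(category = vals, length = lens)
}

#' Compare the genome partitions induced by two graphs of the same pair
#'
#' Each graph labels every position of each genome as shared (in a block
#' containing both genomes) or private; the overlay of the two labellings
#' is classified as agree-shared, agree-private or disagree.
#'
#' @param graph_a,graph_b `pangraph`s containing exactly the two genomes.
#' @param pair Character vector of the two genome names.
#' @param circular Treat genomes as circular when merging boundary
#'   segments? (Default `TRUE`.)
#' @return A tibble with one row per genome and category: fraction of
#'   genome length and mean segment length.
#' @export
partition_compare <- function(graph_a, graph_b, pair, circular = TRUE) {
  stopifnot(length(pair) == 2L)
  iva <- partition_intervals(graph_a, pair)
  ivb <- partition_intervals(graph_b, pair)
  rows <- lapply(pair, function(nm) {
    L <- max(iva[[nm]]$end)
    stopifnot(L == max(ivb[[nm]]$end))
    la <- rotate_labels(label_positions(iva[[nm]], L),
                        graph_a$paths[[nm]]$offset %||% 0L)
    lb <- rotate_labels(label_positions(ivb[[nm]], L),
                        graph_b$paths[[nm]]$offset %||% 0L)
    cat <- ifelse(la != lb, "disagree",
                  ifelse(la, "agree_shared", "agree_private"))
    runs <- segment_runs(cat, circular)
    agg <- dplyr::summarise(
      dplyr::group_by(runs, .data$category),
      fraction = sum(.data$length) / L,
      mean_segment_length = mean(.data$length),
      n_segments = dplyr::n(), .groups = "drop")
    full <- tibble::tibble(category = c("agree_shared", "agree_private",
                                        "disagree"))
    out <- dplyr::left_join(full, agg, by = "category")
    out$fraction[is.na(out$fraction)] <- 0
    out$genome <- nm
    out
  })
  dplyr::relocate(dplyr::bind_rows(rows), "genome")
}

#' Divergence-corrected shared-sequence estimate from k-mers
#'
#' The fraction of shared canonical k-mers (relative to the smaller k-mer
#' set) is divided by `(1 - d)^k` to correct for k-mers on homologous
#' sequence broken by mutations, where `d` is the core divergence of the
#' pair.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param divergence Average pairwise (core) divergence `d` in \[0, 1).
#' @param cfg A [metrics_config()] (supplies `k`).
#' @return Estimated shared fraction, capped at 1 (with a warning when
#'   the raw estimate exceeds 1).
#' @export
shared_sequence_estimate <- function(seq_a, seq_b, divergence = 0,
                                     cfg = metrics_config()) {
  stopifnot(nzchar(seq_a), nzchar(seq_b), divergence >= 0, divergence < 1)
  ka <- unique(canonical_kmer_codes(seq_a, cfg$kmer))
  kb <- unique(canonical_kmer_codes(seq_b, cfg$kmer))
  ka <- ka[!is.na(ka)]; kb <- kb[!is.na(kb)]
  shared <- sum(ka %in% kb)
  raw <- shared / min(length(ka), length(kb))
  est <- raw / (1 - divergence)^cfg$kmer
  if (est > 1) {
    warning("shared-sequence estimate exceeded 1 (", signif(est, 4),
            "); capped")
    est <- 1
  }
  est
}
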