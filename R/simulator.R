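# Wright-Fisher forward simulator of genome populations with nucleotide
# substitutions, inversions, deletions and horizontal sequence transfer.
#
# Each individual is tracked as an ordered decomposition of its genome into
# ancestral intervals (0-based half-open coordinates on the founder genome,
# orientation +/-) plus a substitution list in current coordinates.  The
# decomposition tiles the genome exactly, so the true block structure and
# breakpoints are available without re-alignment.

#' Simulation parameters
#'
#' @param n Population size (number of genomes).
#' @param len Initial genome length in bp.
#' @param generations Number of Wright-Fisher generations (default 50).
#' @param mu Substitution rate per site per generation (genome rate is
#'   `mu * len`).
#' @param inv_rate Inversions per genome per generation (default 0.01).
#' @param del_rate Deletions per genome per generation (default 0.05).
#' @param hgt_rate Horizontal transfer events per genome per generation
#'   (default 0.05).
#' @param inv_mean,del_mean,hgt_mean Mean event lengths in bp (geometric
#'   distributions; defaults 5000, 500, 5000).
#' @param min_genome_length Floor below which deletions are skipped with a
#'   warning (default 1000 bp).
#' @param circular Simulate circular chromosomes? (Default `TRUE`.)
#' @return A `sim_params` list.
#' @export
sim_params <- function(n = 10L, len = 100000L, generations = 50L,
                       mu = 5e-4, inv_rate = 0.01, del_rate = 0.05,
                       hgt_rate = 0.05, inv_mean = 5000, del_mean = 500,
                       hgt_mean = 5000, min_genome_length = 1000L,
                       circular = TRUE) {
  stopifnot(n >= 1L, len >= 1L, generations >= 0L, mu >= 0, inv_rate >= 0,
            del_rate >= 0, hgt_rate >= 0)
  structure(list(n = as.integer(n), len = as.integer(len),
                 generations = as.integer(generations), mu = mu,
                 inv_rate = inv_rate, del_rate = del_rate,
                 hgt_rate = hgt_rate, inv_mean = inv_mean,
                 del_mean = del_mean, hgt_mean = hgt_mean,
                 min_genome_length = as.integer(min_genome_length),
                 circular = circular),
            class = "sim_params")
}

#' Per-site substitution rate targeting an average pairwise divergence
#'
#' In a Wright-Fisher population of size `n` observed after `t`
#' generations, the expected pairwise coalescence time is
#' `n * (1 - (1 - 1/n)^t)` generations, so the expected raw divergence of
#' a pair is twice that times the per-site rate.  A Jukes-Cantor
#' correction maps the requested observed divergence to raw substitutions
#' per site.
#'
#' @param divergence Target average pairwise divergence (fraction).
#' @param n Population size.
#' @param t Generations.
#' @return Substitution rate per site per generation.
#' @export
mutation_rate_for_divergence <- function(divergence, n, t) {
  stopifnot(divergence >= 0, divergence < 0.75)
  d_raw <- -0.75 * log(1 - 4 * divergence / 3)
  e_pair <- n * (1 - (1 - 1 / n)^t)
  d_raw / (2 * e_pair)
}

new_individual <- function(len) {
  list(iv = list(astart = 0L, aend = as.integer(len), orient = "+"),
       sub_pos = integer(0), sub_base = character(0))
}

ind_length <- function(ind) sum(ind$iv$aend - ind$iv$astart)

# split the interval decomposition at current coordinate `pos` (0 <= pos <=
# length); returns the individual with a junction exactly at pos
ind_cut_at <- function(ind, pos) {
  lens <- ind$iv$aend - ind$iv$astart
  cum <- cumsum(lens)
  if (pos == 0L || pos == cum[length(cum)]) return(ind)
  i <- findInterval(pos, c(0L, cum), rightmost.closed = FALSE)  # interval index
  start_i <- if (i > 1L) cum[i - 1L] else 0L
  off <- pos - start_i
  if (off == 0L) return(ind)
  a <- ind$iv$astart[i]; b <- ind$iv$aend[i]; o <- ind$iv$orient[i]
  if (o == "+") {
    left <- c(a, a + off); right <- c(a + off, b)
  } else {
    left <- c(b - off, b); right <- c(a, b - off)
  }
  ind$iv <- list(
    astart = append(ind$iv$astart[-i], c(left[1], right[1]), after = i - 1L),
    aend = append(ind$iv$aend[-i], c(left[2], right[2]), after = i - 1L),
    orient = append(ind$iv$orient[-i], c(o, o), after = i - 1L))
  ind
}

# extract intervals + subs covering current coords [s, e); also returns the
# remainder individual with the range removed
ind_slice <- function(ind, s, e) {
  ind <- ind_cut_at(ind, s)
  ind <- ind_cut_at(ind, e)
  lens <- ind$iv$aend - ind$iv$astart
  cum <- cumsum(lens)
  starts <- c(0L, cum[-length(cum)])
  sel <- starts >= s & cum <= e
  inside <- list(astart = ind$iv$astart[sel], aend = ind$iv$aend[sel],
                 orient = ind$iv$orient[sel])
  ssel <- ind$sub_pos >= s & ind$sub_pos < e
  list(
    inside = inside,
    sub_pos = ind$sub_pos[ssel] - s, sub_base = ind$sub_base[ssel],
    rest = local({
      r <- ind
      r$iv <- list(astart = ind$iv$astart[!sel], aend = ind$iv$aend[!sel],
                   orient = ind$iv$orient[!sel])
      keep <- !ssel
      r$sub_pos <- ind$sub_pos[keep]
      r$sub_base <- ind$sub_base[keep]
      shift <- r$sub_pos >= e
      r$sub_pos[shift] <- r$sub_pos[shift] - (e - s)
      r
    }))
}

# insert intervals/subs at current coordinate s of ind (which must already
# lack the range, i.e. use after ind_slice$rest)
ind_insert <- function(ind, s, piece_iv, piece_sub_pos, piece_sub_base) {
  lens <- ind$iv$aend - ind$iv$astart
  cum <- c(0L, cumsum(lens))
  i <- match(s, cum)  # junction index; guaranteed by prior cuts
  if (is.na(i)) stop("internal: insertion point is not a junction")
  at <- i - 1L
  ind$iv <- list(
    astart = append(ind$iv$astart, piece_iv$astart, after = at),
    aend = append(ind$iv$aend, piece_iv$aend, after = at),
    orient = append(ind$iv$orient, piece_iv$orient, after = at))
  plen <- sum(piece_iv$aend - piece_iv$astart)
  shift <- ind$sub_pos >= s
  ind$sub_pos[shift] <- ind$sub_pos[shift] + plen
  ind$sub_pos <- c(ind$sub_pos, piece_sub_pos + s)
  ind$sub_base <- c(ind$sub_base, piece_sub_base)
  o <- order(ind$sub_pos)
  ind$sub_pos <- ind$sub_pos[o]; ind$sub_base <- ind$sub_base[o]
  ind
}

apply_inversion <- function(ind, s, e) {
  sl <- ind_slice(ind, s, e)
  iv <- sl$inside
  k <- length(iv$astart)
  inv <- list(astart = rev(iv$astart), aend = rev(iv$aend),
              orient = rev(ifelse(iv$orient == "+", "-", "+")))
  # substitutions inside reflect and complement
  sp <- (e - s) - 1L - sl$sub_pos
  sb <- complement_chars(sl$sub_base)
  ind_insert(sl$rest, s, inv, sp, sb)
}

apply_deletion <- function(ind, s, e) ind_slice(ind, s, e)$rest

apply_hgt <- function(ind, donor, s, e) {
  dsl <- ind_slice(donor, s, e)
  rsl <- ind_slice(ind, s, e)
  ind_insert(rsl$rest, s, dsl$inside, dsl$sub_pos, dsl$sub_base)
}

# sequence of an individual given the founder sequence
ind_sequence <- function(ind, ancestor) {
  k <- length(ind$iv$astart)
  segs <- character(k)
  for (i in seq_len(k)) {
    s <- substr(ancestor, ind$iv$astart[i] + 1L, ind$iv$aend[i])
    if (ind$iv$orient[i] == "-") s <- revcomp(s)
    segs[i] <- s
  }
  seq <- paste(segs, collapse = "")
  if (length(ind$sub_pos)) {
    v <- seq_chars(seq)
    v[ind$sub_pos + 1L] <- ind$sub_base
    seq <- paste(v, collapse = "")
  }
  seq
}

# current base at positions `pos` (vectorized), without building the string
ind_bases_at <- function(ind, ancestor_chars, pos) {
  lens <- ind$iv$aend - ind$iv$astart
  cum <- cumsum(lens)
  i <- findInterval(pos, c(0L, cum), rightmost.closed = FALSE)
  start_i <- c(0L, cum)[i]
  off <- pos - start_i
  fwd <- ind$iv$orient[i] == "+"
  apos <- ifelse(fwd, ind$iv$astart[i] + off, ind$iv$aend[i] - 1L - off)
  base <- ancestor_chars[apos + 1L]
  base[!fwd] <- complement_chars(base[!fwd])
  if (length(ind$sub_pos)) {
    m <- match(pos, ind$sub_pos)
    hit <- !is.na(m)
    base[hit] <- ind$sub_base[m[hit]]
  }
  base
}

geom_len <- function(n, mean) {
  stats::rgeom(n, prob = 1 / mean) + 1L
}

#' Simulate a Wright-Fisher population with structural variation
#'
#' Each generation, every child copies a uniformly chosen parent and then
#' receives Poisson numbers of inversions, deletions, horizontal-transfer
#' replacements and substitutions.  Event segments are contiguous,
#' non-wrapping, with geometric lengths; a horizontal transfer replaces
#' the recipient's segment with the donor's segment at the same
#' coordinates.  Ancestral-interval bookkeeping is updated through every
#' event.  Deterministic given `seed`.
#'
#' @param params A [sim_params()].
#' @param seed Integer RNG seed.
#' @return A list with `genomes` (named character vector), `truth` (a
#'   `pangraph_truth` object: founder sequence, per-genome ancestral
#'   intervals and substitution lists), and `events` (tibble event log).
#' @export
simulate_population <- function(params = sim_params(), seed = 1L) {
  withr::local_seed(as.integer(seed))
  n <- params$n
  ancestor <- random_sequence(params$len)
  anc_chars <- seq_chars(ancestor)
  pop <- replicate(n, new_individual(params$len), simplify = FALSE)
  events <- list()
  log_event <- function(gen, child, type, s, e, donor = NA_integer_) {
    events[[length(events) + 1L]] <<- list(gen = gen, child = child,
                                           type = type, start = s, end = e,
                                           donor = donor)
  }
  for (gen in seq_len(params$generations)) {
    parents <- sample.int(n, n, replace = TRUE)
    newpop <- pop[parents]
    for (i in seq_len(n)) {
      log_event(gen, i, "birth", 0L, 0L, parents[i])
      ind <- newpop[[i]]
      L <- ind_length(ind)
      # inversions
      for (k in seq_len(stats::rpois(1L, params$inv_rate))) {
        l <- min(geom_len(1L, params$inv_mean), L - 1L)
        s <- sample.int(L - l + 1L, 1L) - 1L
        ind <- apply_inversion(ind, s, s + l)
        log_event(gen, i, "inversion", s, s + l)
      }
      # deletions
      for (k in seq_len(stats::rpois(1L, params$del_rate))) {
        L <- ind_length(ind)
        l <- geom_len(1L, params$del_mean)
        if (L - l < params$min_genome_length) {
          warning("deletion skipped: genome at the configured length floor")
          next
        }
        s <- sample.int(L - l + 1L, 1L) - 1L
        ind <- apply_deletion(ind, s, s + l)
        log_event(gen, i, "deletion", s, s + l)
      }
      # horizontal transfer (donor from the parent generation)
      for (k in seq_len(stats::rpois(1L, params$hgt_rate))) {
        L <- ind_length(ind)
        donor_i <- sample.int(n, 1L)
        donor <- pop[[donor_i]]
        Ld <- ind_length(donor)
        l <- min(geom_len(1L, params$hgt_mean), L - 1L, Ld - 1L)
        s <- sample.int(min(L, Ld) - l + 1L, 1L) - 1L
        ind <- apply_hgt(ind, donor, s, s + l)
        log_event(gen, i, "hgt", s, s + l, donor_i)
      }
      # substitutions
      L <- ind_length(ind)
      m <- stats::rpois(1L, params$mu * L)
      if (m > 0L) {
        pos <- sample.int(L, m, replace = TRUE) - 1L
        cur <- ind_bases_at(ind, anc_chars, pos)
        codes <- match(cur, c("A", "C", "G", "T")) - 1L
        newc <- (codes + sample.int(3L, m, replace = TRUE)) %% 4L
        newb <- c("A", "C", "G", "T")[newc + 1L]
        keepold <- !(ind$sub_pos %in% pos)
        ind$sub_pos <- c(ind$sub_pos[keepold], pos)
        ind$sub_base <- c(ind$sub_base[keepold], newb)
        dup <- duplicated(ind$sub_pos, fromLast = TRUE)
        ind$sub_pos <- ind$sub_pos[!dup]; ind$sub_base <- ind$sub_base[!dup]
        o <- order(ind$sub_pos)
        ind$sub_pos <- ind$sub_pos[o]; ind$sub_base <- ind$sub_base[o]
        events[[length(events) + 1L]] <- tibble::tibble(
          gen = gen, child = i, type = "substitution",
          start = pos, end = pos + 1L, donor = NA_integer_)
      }
      newpop[[i]] <- ind
    }
    pop <- newpop
  }
  nms <- sprintf("iso_%02d", seq_len(n))
  genomes <- vapply(pop, ind_sequence, character(1), ancestor = ancestor)
  names(genomes) <- nms
  names(pop) <- nms
  truth <- structure(list(ancestor = ancestor, individuals = pop,
                          circular = params$circular, params = params),
                     class = "pangraph_truth")
  ev <- if (length(events)) dplyr::bind_rows(lapply(events, tibble::as_tibble))
        else tibble::tibble(gen = integer(0), child = integer(0),
                            type = character(0), start = integer(0),
                            end = integer(0), donor = integer(0))
  list(genomes = genomes, truth = truth, events = ev)
}

#' @export
print.pangraph_truth <- function(x, ...) {
  cat(sprintf("<pangraph_truth> founder %s bp, %d genome(s)%s\n",
              format(nchar(x$ancestor), big.mark = ","),
              length(x$individuals),
              if (x$circular) ", circular" else ""))
  invisible(x)
}

#' True breakpoints of simulated genomes
#'
#' Junctions between maximal runs of ancestrally contiguous, co-oriented
#' sequence, in extant-genome coordinates.  For circular genomes the
#' origin junction counts only if it is not ancestrally contiguous; for
#' linear genomes the origin (position 0) is always reported.
#'
#' @param truth A `pangraph_truth` from [simulate_population()].
#' @return Named list of sorted integer breakpoint positions per genome.
#' @export
true_breakpoints <- function(truth) {
  L0 <- nchar(truth$ancestor)
  lapply(truth$individuals, function(ind) {
    iv <- ind$iv
    k <- length(iv$astart)
    lens <- iv$aend - iv$astart
    cum <- cumsum(lens)
    if (k == 0L) return(integer(0))
    bp <- integer(0)
    contiguous <- function(i, j) {
      if (iv$orient[i] != iv$orient[j]) return(FALSE)
      if (iv$orient[i] == "+") {
        iv$aend[i] == iv$astart[j] ||
          (truth$circular && iv$aend[i] == L0 && iv$astart[j] == 0L)
      } else {
        iv$astart[i] == iv$aend[j] ||
          (truth$circular && iv$astart[i] == 0L && iv$aend[j] == L0)
      }
    }
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        if (!contiguous(i, i + 1L)) bp <- c(bp, cum[i])
      }
    }
    if (truth$circular) {
      if (k > 1L || !contiguous(k, 1L)) {
        if (!contiguous(k, 1L)) bp <- c(bp, 0L)
      }
    } else {
      bp <- c(bp, 0L)
    }
    sort(unique(bp))
  })
}

#' Convert simulation truth into the true pangenome graph
#'
#' Ancestor coordinates are cut at every interval boundary observed in any
#' genome; the resulting ancestral segments become pancontigs (consensus =
#' founder sequence), and each genome's path walks its intervals through
#' those segments with its substitutions attached as edits.  Because a
#' junction in any one genome refines the block structure of every path,
#' this is the graph a perfect aligner would reconstruct, and its
#' breakpoints are directly comparable with a built graph's.
#'
#' @param truth A `pangraph_truth` from [simulate_population()].
#' @param compact Merge transitive chains? (Default `TRUE`.)  Compaction
#'   removes junctions shared identically by every genome (fixed events),
#'   which no aligner could reconstruct from the extant sequences; with
#'   `compact = FALSE` every ancestral junction is kept.
#' @return A `pangraph`; reconstructing it reproduces every simulated
#'   genome exactly.
#' @export
true_pangraph <- function(truth, compact = TRUE) {
  L0 <- nchar(truth$ancestor)
  cuts <- sort(unique(c(0L, L0, unlist(lapply(truth$individuals, function(ind) {
    c(ind$iv$astart, ind$iv$aend)
  })))))
  seg_start <- cuts[-length(cuts)]
  seg_end <- cuts[-1L]
  seg_of <- function(pos) findInterval(pos, seg_start)
  blocks <- list(); nodes <- list(); paths <- list()
  used <- logical(length(seg_start))
  bid_of <- sprintf("T%06d", seq_along(seg_start))
  for (nm in names(truth$individuals)) {
    ind <- truth$individuals[[nm]]
    nids <- character(0)
    cur <- 0L  # current-genome coordinate at the start of the next piece
    step <- 0L
    for (i in seq_along(ind$iv$astart)) {
      a <- ind$iv$astart[i]; b <- ind$iv$aend[i]; o <- ind$iv$orient[i]
      inner <- cuts[cuts > a & cuts < b]
      bounds <- c(a, inner, b)
      k <- length(bounds) - 1L
      pieces <- seq_len(k)
      if (o == "-") pieces <- rev(pieces)
      for (pi in pieces) {
        p1 <- bounds[pi]; p2 <- bounds[pi + 1L]
        si <- seg_of(p1)
        used[si] <- TRUE
        step <- step + 1L
        nid <- paste0(nm, ":", step)
        plen <- p2 - p1
        ssel <- ind$sub_pos >= cur & ind$sub_pos < cur + plen
        sp <- ind$sub_pos[ssel] - cur
        sb <- ind$sub_base[ssel]
        if (o == "-") {
          sp <- plen - 1L - sp
          sb <- complement_chars(sb)
        }
        ed <- make_edits(sub_pos = sp, sub_base = sb)
        if (is.null(blocks[[bid_of[si]]])) {
          blocks[[bid_of[si]]] <- list(
            id = bid_of[si],
            consensus = substr(truth$ancestor, p1 + 1L, p2),
            nodes = list())
        }
        blocks[[bid_of[si]]]$nodes[[nid]] <- ed
        nodes[[nid]] <- list(block = bid_of[si], path = nm, strand = o)
        nids <- c(nids, nid)
        cur <- cur + plen
      }
    }
    paths[[nm]] <- list(name = nm, nodes = nids, circular = truth$circular,
                        offset = 0L)
  }
  g <- new_pangraph(blocks, nodes, paths)
  if (compact) merge_transitive(g) else g
}
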