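# Pairwise homology search between pancontig consensus sequences.
#
# Hits follow PAF conventions: query/ref intervals are 0-based half-open on
# the forward strand of each consensus; for strand "-" the cigar describes
# the reverse-complemented query aligned left-to-right against the forward
# reference.  Cigars use =/X/I/D, with I consuming query and D consuming
# reference.

#' Alignment kernel configuration
#'
#' @param kernel `"minimap2"` (external binary), `"builtin"`
#'   (dependency-free anchor/chain kernel), or `"mmseqs2"` (adapter slot,
#'   not implemented).
#' @param preset For minimap2: `"asm20"` (default) or `"asm10"`; ignored
#'   by the builtin kernel.
#' @param min_length Hits shorter than this many alignment columns are
#'   dropped at the kernel boundary (default 100 bp).
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(kernel = c("minimap2", "builtin", "mmseqs2"),
                          preset = NULL, min_length = 100L) {
  kernel <- match.arg(kernel)
  preset <- preset %||% switch(kernel, minimap2 = "asm20", "builtin-default")
  if (kernel == "minimap2" && !preset %in% c("asm5", "asm10", "asm20"))
    stop("invalid minimap2 preset: ", preset)
  structure(list(kernel = kernel, preset = preset,
                 min_length = as.integer(min_length)),
            class = "kernel_config")
}

empty_hits <- function() {
  tibble::tibble(query = character(0), qlen = integer(0), qstart = integer(0),
                 qend = integer(0), strand = character(0), ref = character(0),
                 rlen = integer(0), rstart = integer(0), rend = integer(0),
                 matches = integer(0), length = integer(0), cigar = character(0),
                 divergence = numeric(0))
}

# --- cigar utilities -------------------------------------------------------

parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) stop("malformed cigar: empty")
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0L)
    stop("malformed cigar: ", cigar)
  if (!all(ops %in% c("=", "X", "I", "D", "M")))
    stop("unsupported cigar operation in: ", cigar)
  list(len = lens, op = ops)
}

cigar_string <- function(ops) {
  keep <- ops$len > 0L
  len <- ops$len[keep]; op <- ops$op[keep]
  if (length(op) > 1L) {  # coalesce equal adjacent ops
    grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
    len <- as.integer(tapply(len, grp, sum))
    op <- op[!duplicated(grp)]
  }
  paste0(len, op, collapse = "")
}

cigar_span <- function(ops) {
  list(query = sum(ops$len[ops$op %in% c("=", "X", "I", "M")]),
       ref = sum(ops$len[ops$op %in% c("=", "X", "D", "M")]),
       columns = sum(ops$len))
}

#' Divergence of a hit from its cigar
#'
#' The polymorphism count is the number of mismatch columns plus the
#' number of indel events (each indel counts once regardless of length);
#' divergence is that count divided by the number of alignment columns.
#' Requires an unambiguous cigar (`=`/`X`, not `M`).
#'
#' @param cigar A cigar string with `=`/`X`/`I`/`D` operations.
#' @return Fraction in \[0, 1\].
#' @export
divergence_from_cigar <- function(cigar) {
  ops <- parse_cigar(cigar)
  if (any(ops$op == "M"))
    stop("ambiguous cigar (M): rerun the kernel with =/X operations")
  n_m <- sum(ops$len[ops$op == "X"]) + sum(ops$op %in% c("I", "D"))
  n_m / sum(ops$len)
}

cigar_polymorphisms <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op == "X"]) + sum(ops$op %in% c("I", "D"))
}

# Check that a hit's cigar is consistent with its intervals and realizes the
# stated match count against the actual sequences.
validate_hit <- function(hit, qseq, rseq) {
  ops <- parse_cigar(hit$cigar)
  sp <- cigar_span(ops)
  if (sp$query != hit$qend - hit$qstart) return(FALSE)
  if (sp$ref != hit$rend - hit$rstart) return(FALSE)
  q <- substr(qseq, hit$qstart + 1L, hit$qend)
  if (hit$strand == "-") q <- revcomp(q)
  r <- substr(rseq, hit$rstart + 1L, hit$rend)
  qv <- seq_chars(q); rv <- seq_chars(r)
  qi <- 0L; ri <- 0L; matches <- 0L
  for (i in seq_along(ops$op)) {
    l <- ops$len[i]
    switch(ops$op[i],
      "=" = {
        if (!identical(qv[qi + seq_len(l)], rv[ri + seq_len(l)])) return(FALSE)
        matches <- matches + l; qi <- qi + l; ri <- ri + l
      },
      "X" = {
        if (any(qv[qi + seq_len(l)] == rv[ri + seq_len(l)])) return(FALSE)
        qi <- qi + l; ri <- ri + l
      },
      "M" = {
        matches <- matches + sum(qv[qi + seq_len(l)] == rv[ri + seq_len(l)])
        qi <- qi + l; ri <- ri + l
      },
      "I" = qi <- qi + l,
      "D" = ri <- ri + l)
  }
  TRUE
}

# --- minimap2 adapter ------------------------------------------------------

minimap2_available <- function() nzchar(Sys.which("minimap2"))

run_minimap2 <- function(ref_seqs, qry_seqs, preset) {
  if (!minimap2_available()) {
    stop("alignment kernel 'minimap2' unavailable (binary not on PATH); ",
         "use kernel_config(kernel = \"builtin\") as the fallback")
  }
  rf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(rf, qf)), add = TRUE)
  write_fasta(ref_seqs, rf)
  if (identical(names(ref_seqs), names(qry_seqs)) &&
      identical(unname(ref_seqs), unname(qry_seqs))) {
    qf <- rf
  } else {
    qf <- tempfile(fileext = ".fa")
    write_fasta(qry_seqs, qf)
  }
  out <- suppressWarnings(system2(
    "minimap2", c("-c", "--eqx", "-t", "1", "-x", preset,
                  "-X", "-N", "100", "-p", "0.1", shQuote(rf), shQuote(qf)),
    stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) stop("minimap2 failed with status ", status)
  parse_paf(out)
}

parse_paf <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) return(NULL)
    cg <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (length(cg) == 0L) return(NULL)  # secondary records without cigar
    tibble::tibble(
      query = f[1], qlen = as.integer(f[2]),
      qstart = as.integer(f[3]), qend = as.integer(f[4]),
      strand = f[5],
      ref = f[6], rlen = as.integer(f[7]),
      rstart = as.integer(f[8]), rend = as.integer(f[9]),
      matches = as.integer(f[10]), length = as.integer(f[11]),
      cigar = sub("^cg:Z:", "", cg[1]))
  })
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0L) return(empty_hits())
  hits$divergence <- vapply(hits$cigar, divergence_from_cigar, numeric(1),
                            USE.NAMES = FALSE)
  hits
}

#' Emit hits as PAF records
#'
#' Standard 12-column PAF plus a `cg:Z:` cigar tag, for debugging and
#' interoperability.
#'
#' @param hits A hit tibble from [align_consensus_sets()].
#' @return Character vector of PAF lines.
#' @export
hits_to_paf <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\tcg:Z:%s",
          hits$query, hits$qlen, hits$qstart, hits$qend, hits$strand,
          hits$ref, hits$rlen, hits$rstart, hits$rend,
          hits$matches, hits$length, 60L, hits$cigar)
}

# --- builtin kernel --------------------------------------------------------
# Unique-k-mer anchors, collinear chaining, affine-gap fill between anchors.

builtin_anchor_positions <- function(seq, k) {
  codes <- encode_kmers(seq, k)
  ok <- which(!is.na(codes))
  cc <- codes[ok]
  dup <- cc %in% cc[duplicated(cc)]
  list(code = cc[!dup], pos = ok[!dup] - 1L)  # 0-based start positions
}

# Align qseq (forward) against rseq (forward); returns hit rows (strand "+").
builtin_align_forward <- function(qseq, rseq, k = 15L, min_length = 100L,
                                  max_gap = 5000L, band = 500L) {
  qa <- builtin_anchor_positions(qseq, k)
  ra <- builtin_anchor_positions(rseq, k)
  m <- match(qa$code, ra$code)
  sel <- !is.na(m)
  if (!any(sel)) return(empty_hits())
  qp <- qa$pos[sel]; rp <- ra$pos[m[sel]]
  o <- order(qp)
  qp <- qp[o]; rp <- rp[o]
  # greedy collinear chaining: split whenever ref order breaks, the diagonal
  # jumps by more than `band`, or the gap exceeds `max_gap`
  brk <- c(TRUE, diff(rp) <= 0 | abs(diff(rp - qp)) > band | diff(qp) > max_gap)
  chain_id <- cumsum(brk)
  hits <- list()
  for (cid in unique(chain_id)) {
    idx <- which(chain_id == cid)
    if (length(idx) == 0L) next
    h <- builtin_chain_to_hit(qp[idx], rp[idx], k, qseq, rseq)
    if (!is.null(h) && h$length >= min_length) hits[[length(hits) + 1L]] <- h
  }
  if (length(hits) == 0L) return(empty_hits())
  dplyr::bind_rows(hits)
}

builtin_chain_to_hit <- function(qp, rp, k, qseq, rseq) {
  # overlapping anchors are trimmed so both coordinates advance strictly
  ops_len <- integer(0); ops_op <- character(0)
  push <- function(l, o) {
    if (l > 0L) { ops_len <<- c(ops_len, l); ops_op <<- c(ops_op, o) }
  }
  q0 <- qp[1]; r0 <- rp[1]
  qcur <- qp[1]; rcur <- rp[1]  # current exact-run start
  qend <- qp[1] + k; rend <- rp[1] + k
  for (i in seq_along(qp)[-1]) {
    qs <- qp[i]; rs <- rp[i]
    adv <- max(0L, qend - qs, rend - rs)
    qs <- qs + adv; rs <- rs + adv
    if (qs >= qp[i] + k || rs >= rp[i] + k) next  # fully swallowed anchor
    if (qs == qend && rs == rend) {
      qend <- qp[i] + k; rend <- rp[i] + k
      next
    }
    # close the running exact match, fill the gap
    push(qend - qcur, "=")
    gq <- qs - qend; gr <- rs - rend
    if (gq > 0L && gr > 0L) {
      sub <- align_gap(substr(qseq, qend + 1L, qs), substr(rseq, rend + 1L, rs))
      if (is.null(sub)) return(NULL)
      ops_len <- c(ops_len, sub$len); ops_op <- c(ops_op, sub$op)
    } else if (gq > 0L) push(gq, "I") else if (gr > 0L) push(gr, "D")
    qcur <- qs; rcur <- rs
    qend <- qp[i] + k; rend <- rp[i] + k
  }
  push(qend - qcur, "=")
  ops <- list(len = ops_len, op = ops_op)
  cg <- cigar_string(ops)
  ops <- parse_cigar(cg)
  matches <- sum(ops$len[ops$op == "="])
  cols <- sum(ops$len)
  tibble::tibble(query = NA_character_, qlen = nchar(qseq),
                 qstart = q0, qend = qend, strand = "+",
                 ref = NA_character_, rlen = nchar(rseq),
                 rstart = r0, rend = rend,
                 matches = matches, length = cols, cigar = cg,
                 divergence = divergence_from_cigar(cg))
}

# affine-gap global alignment of two short gap segments -> cigar ops
align_gap <- function(q, r, max_len = 5000L) {
  if (nchar(q) > max_len || nchar(r) > max_len) return(NULL)
  aln <- Biostrings::pairwiseAlignment(
    pattern = q, subject = r, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 0.5)
  pv <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sv <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  op <- ifelse(pv == "-", "D", ifelse(sv == "-", "I",
               ifelse(pv == sv, "=", "X")))
  r <- rle(op)
  list(len = r$lengths, op = r$values)
}

builtin_align_pair <- function(qseq, rseq, cfg) {
  fw <- builtin_align_forward(qseq, rseq, min_length = cfg$min_length)
  rcq <- revcomp(qseq)
  rv <- builtin_align_forward(rcq, rseq, min_length = cfg$min_length)
  if (nrow(rv)) {
    Lq <- nchar(qseq)
    qs <- Lq - rv$qend
    qe <- Lq - rv$qstart
    rv$qstart <- qs; rv$qend <- qe
    rv$strand <- "-"
  }
  dplyr::bind_rows(fw, rv)
}

# --- kernel front end ------------------------------------------------------

#' All-to-all consensus alignment of two pancontig sets
#'
#' Finds homologous intervals between the consensus sequences of `blocksA`
#' (queries) and `blocksB` (references).  The two sets may be identical
#' (self-alignment, to capture duplications); trivial identity self-hits
#' and mirrored duplicates are removed, and hits shorter than
#' `cfg$min_length` columns are dropped.
#'
#' @param blocksA,blocksB Lists of pancontigs (`graph$blocks` style), or a
#'   named character vector of sequences.
#' @param cfg A [kernel_config()].
#' @return A hit tibble (PAF-convention coordinates, `=`/`X` cigars,
#'   per-hit divergence).
#' @export
align_consensus_sets <- function(blocksA, blocksB = blocksA,
                                 cfg = kernel_config()) {
  seqsA <- blocks_to_seqs(blocksA)
  seqsB <- blocks_to_seqs(blocksB)
  stopifnot(length(seqsA) > 0L, length(seqsB) > 0L)
  if (cfg$kernel == "mmseqs2")
    stop("alignment kernel 'mmseqs2' is an adapter slot and is not ",
         "implemented; use \"minimap2\" or \"builtin\"")
  hits <- if (cfg$kernel == "minimap2") {
    run_minimap2(seqsB, seqsA, cfg$preset)
  } else {
    out <- list()
    same <- identical(names(seqsA), names(seqsB)) &&
      identical(unname(seqsA), unname(seqsB))
    for (qn in names(seqsA)) {
      for (rn in names(seqsB)) {
        if (qn == rn) next  # builtin kernel: no within-sequence self-hits
        if (same && qn > rn) next  # avoid mirrored duplicates up front
        h <- builtin_align_pair(seqsA[[qn]], seqsB[[rn]], cfg)
        if (nrow(h)) { h$query <- qn; h$ref <- rn; out[[length(out) + 1L]] <- h }
      }
    }
    if (length(out)) dplyr::bind_rows(out) else empty_hits()
  }
  if (nrow(hits) == 0L) return(empty_hits())
  # drop trivial identity self-hits
  triv <- hits$query == hits$ref & hits$qstart == hits$rstart &
    hits$qend == hits$rend & hits$strand == "+"
  hits <- hits[!triv, , drop = FALSE]
  # deduplicate mirrored hits (X->Y vs Y->X)
  key <- ifelse(
    hits$query < hits$ref |
      (hits$query == hits$ref & (hits$qstart < hits$rstart |
        (hits$qstart == hits$rstart & hits$qend <= hits$rend))),
    paste(hits$query, hits$qstart, hits$qend, hits$ref, hits$rstart,
          hits$rend, hits$strand),
    paste(hits$ref, hits$rstart, hits$rend, hits$query, hits$qstart,
          hits$qend, hits$strand))
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[hits$length >= cfg$min_length, , drop = FALSE]
  dplyr::arrange(hits, .data$query, .data$ref, .data$qstart, .data$rstart)
}

blocks_to_seqs <- function(blocks) {
  if (is.character(blocks)) {
    stopifnot(!is.null(names(blocks)))
    return(blocks)
  }
  stats::setNames(
    vapply(blocks, function(b) b$consensus, character(1)),
    vapply(blocks, function(b) b$id, character(1)))
}
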