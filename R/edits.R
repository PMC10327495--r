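# Edit lists: per-occurrence differences from a block consensus.
#
# Coordinates are 0-based on the block consensus.  Substitutions sit at a
# single position, deletions cover [pos, pos+len), and insertions occupy the
# gap slot *before* consensus position pos (slot L means "after the last
# base").  Edits of one occurrence are kept sorted and non-overlapping.

empty_edits <- function() {
  list(sub_pos = integer(0), sub_base = character(0),
       ins_pos = integer(0), ins_seq = character(0),
       del_pos = integer(0), del_len = integer(0))
}

make_edits <- function(sub_pos = integer(0), sub_base = character(0),
                       ins_pos = integer(0), ins_seq = character(0),
                       del_pos = integer(0), del_len = integer(0)) {
  o <- order(sub_pos)
  s <- order(ins_pos)
  d <- order(del_pos)
  list(sub_pos = as.integer(sub_pos[o]), sub_base = as.character(sub_base[o]),
       ins_pos = as.integer(ins_pos[s]), ins_seq = as.character(ins_seq[s]),
       del_pos = as.integer(del_pos[d]), del_len = as.integer(del_len[d]))
}

edits_empty <- function(ed) {
  length(ed$sub_pos) + length(ed$ins_pos) + length(ed$del_pos) == 0L
}

edits_count <- function(ed) {
  length(ed$sub_pos) + length(ed$ins_pos) + length(ed$del_pos)
}

validate_edits <- function(ed, L) {
  if (length(ed$sub_pos)) {
    if (any(ed$sub_pos < 0L | ed$sub_pos >= L)) stop("substitution position out of range")
    if (any(nchar(ed$sub_base) != 1L)) stop("substitution payload must be a single base")
  }
  if (length(ed$del_pos)) {
    if (any(ed$del_len < 1L)) stop("deletion length must be >= 1")
    if (any(ed$del_pos < 0L | ed$del_pos + ed$del_len > L)) stop("deletion out of range")
    if (length(ed$del_pos) > 1L) {
      e <- ed$del_pos + ed$del_len
      if (any(ed$del_pos[-1L] < e[-length(e)])) stop("overlapping deletions")
    }
  }
  if (length(ed$ins_pos)) {
    if (any(ed$ins_pos < 0L | ed$ins_pos > L)) stop("insertion slot out of range")
    if (any(!nzchar(ed$ins_seq))) stop("empty insertion payload")
    if (anyDuplicated(ed$ins_pos)) stop("duplicate insertion slots")
  }
  # substitutions must not fall inside a deletion; insertion slots must not
  # fall strictly inside a deletion
  if (length(ed$del_pos)) {
    for (i in seq_along(ed$del_pos)) {
      a <- ed$del_pos[i]; b <- a + ed$del_len[i]
      if (any(ed$sub_pos >= a & ed$sub_pos < b)) stop("substitution inside deletion")
      if (any(ed$ins_pos > a & ed$ins_pos < b)) stop("insertion slot inside deletion")
    }
  }
  invisible(TRUE)
}

# Apply edits to a consensus string, producing the occurrence's segment in
# the consensus-forward frame (strand handling is the caller's business).
apply_edits <- function(consensus, ed) {
  if (edits_empty(ed)) return(consensus)
  L <- nchar(consensus)
  v <- seq_chars(consensus)
  if (length(ed$sub_pos)) v[ed$sub_pos + 1L] <- ed$sub_base
  if (length(ed$del_pos)) {
    for (i in seq_along(ed$del_pos)) {
      v[seq.int(ed$del_pos[i] + 1L, length.out = ed$del_len[i])] <- ""
    }
  }
  ins <- character(L + 1L)
  if (length(ed$ins_pos)) ins[ed$ins_pos + 1L] <- ed$ins_seq
  paste0(paste0(ins[seq_len(L)], v, collapse = ""), ins[L + 1L])
}

# Re-express edits for the reverse-complemented consensus (length L).
flip_edits <- function(ed, L) {
  make_edits(
    sub_pos = L - 1L - ed$sub_pos,
    sub_base = if (length(ed$sub_base)) complement_chars(ed$sub_base) else character(0),
    ins_pos = L - ed$ins_pos,
    ins_seq = vapply(ed$ins_seq, revcomp, character(1), USE.NAMES = FALSE),
    del_pos = L - ed$del_pos - ed$del_len,
    del_len = ed$del_len
  )
}

# Partition edits across consecutive consensus segments delimited by `cuts`
# (strictly inside (0, L), sorted, distinct).  An insertion at slot c goes to
# the right-hand segment (local slot 0); a deletion spanning a cut is split.
# Returns a list of edit lists, one per segment.
split_edits <- function(ed, cuts, L) {
  bounds <- c(0L, as.integer(cuts), L)
  k <- length(bounds) - 1L
  out <- vector("list", k)
  for (i in seq_len(k)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    ssel <- ed$sub_pos >= a & ed$sub_pos < b
    # insertion slot rule: slot in [a, b) belongs here; the final segment also
    # takes slot L
    isel <- ed$ins_pos >= a & (ed$ins_pos < b | (i == k & ed$ins_pos == L))
    dp <- integer(0); dl <- integer(0)
    if (length(ed$del_pos)) {
      ds <- pmax(ed$del_pos, a)
      de <- pmin(ed$del_pos + ed$del_len, b)
      keep <- de > ds
      dp <- ds[keep] - a
      dl <- (de - ds)[keep]
    }
    out[[i]] <- make_edits(
      sub_pos = ed$sub_pos[ssel] - a, sub_base = ed$sub_base[ssel],
      ins_pos = ed$ins_pos[isel] - a, ins_seq = ed$ins_seq[isel],
      del_pos = dp, del_len = dl
    )
  }
  out
}

# Shift all edit coordinates right by `off` (used when concatenating blocks).
shift_edits <- function(ed, off) {
  list(sub_pos = ed$sub_pos + as.integer(off), sub_base = ed$sub_base,
       ins_pos = ed$ins_pos + as.integer(off), ins_seq = ed$ins_seq,
       del_pos = ed$del_pos + as.integer(off), del_len = ed$del_len)
}

concat_edits <- function(ed1, ed2, off) {
  e2 <- shift_edits(ed2, off)
  # an insertion of ed1 at slot off and one of ed2 at local slot 0 land on the
  # same slot; fuse them (ed1 content first: it precedes in the concatenation)
  if (length(ed1$ins_pos) && length(e2$ins_pos)) {
    j <- match(off, ed1$ins_pos)
    j2 <- match(off, e2$ins_pos)
    if (!is.na(j) && !is.na(j2)) {
      e2$ins_seq[j2] <- paste0(ed1$ins_seq[j], e2$ins_seq[j2])
      ed1$ins_pos <- ed1$ins_pos[-j]; ed1$ins_seq <- ed1$ins_seq[-j]
    }
  }
  make_edits(
    sub_pos = c(ed1$sub_pos, e2$sub_pos), sub_base = c(ed1$sub_base, e2$sub_base),
    ins_pos = c(ed1$ins_pos, e2$ins_pos), ins_seq = c(ed1$ins_seq, e2$ins_seq),
    del_pos = c(ed1$del_pos, e2$del_pos), del_len = c(ed1$del_len, e2$del_len)
  )
}

# --- alignment-row machinery ----------------------------------------------
# A block implies a multiple alignment: one column per consensus position
# plus padded columns for insertions.  These helpers build per-member rows
# and convert rows back into edit lists.

# Character row over the consensus positions only (no insertion columns):
# substitutions applied, deletions as "-".
base_row_chars <- function(cons_chars, ed) {
  row <- cons_chars
  if (length(ed$sub_pos)) row[ed$sub_pos + 1L] <- ed$sub_base
  if (length(ed$del_pos)) {
    for (i in seq_along(ed$del_pos)) {
      row[seq.int(ed$del_pos[i] + 1L, length.out = ed$del_len[i])] <- "-"
    }
  }
  row
}

# Derive edits from a full alignment row against a consensus pattern.
# `pattern` and `row` are equal-length character vectors over alignment
# columns; "-" marks a gap.  Positions where pattern != "-" are the new
# consensus positions, in order.
edits_from_row <- function(pattern, row) {
  keepc <- pattern != "-"
  kr <- row[keepc]
  kp <- pattern[keepc]
  sub_i <- which(kr != "-" & kr != kp)
  del_i <- which(kr == "-")
  dp <- integer(0); dl <- integer(0)
  if (length(del_i)) {
    r <- split(del_i, cumsum(c(1L, diff(del_i) != 1L)))
    dp <- vapply(r, function(z) z[1L] - 1L, integer(1), USE.NAMES = FALSE)
    dl <- vapply(r, length, integer(1), USE.NAMES = FALSE)
  }
  ip <- integer(0); is <- character(0)
  gap_i <- which(!keepc & row != "-")
  if (length(gap_i)) {
    slot <- cumsum(keepc)[gap_i]  # 0-based slot in new consensus coords
    # groups sharing a slot merge even when separated by all-gap columns
    key <- tapply(seq_along(gap_i), slot, function(ix) ix, simplify = FALSE)
    ip <- as.integer(names(key))
    is <- vapply(key, function(ix) paste(row[gap_i[ix]], collapse = ""),
                 character(1), USE.NAMES = FALSE)
  }
  make_edits(sub_pos = sub_i - 1L, sub_base = kr[sub_i],
             ins_pos = ip, ins_seq = is, del_pos = dp, del_len = dl)
}

# Majority vote over alignment columns.  `mat` is members x columns.
# Returns the consensus pattern (one char per column, "-" = column dropped).
# A/C/G/T vote individually; ambiguity codes vote only in columns without
# any A/C/G/T; base-vs-gap ties go to the base; base ties go to the
# lexicographically smallest base.
vote_columns <- function(mat) {
  nc <- ncol(mat)
  gap <- colSums(mat == "-")
  best <- character(nc)
  bestn <- integer(nc)
  for (b in c("A", "C", "G", "T")) {
    cnt <- colSums(mat == b)
    upd <- cnt > bestn
    best[upd] <- b
    bestn[upd] <- cnt[upd]
  }
  # columns with no standard base: let other characters (ambiguity codes)
  # vote among themselves
  none <- which(bestn == 0L)
  if (length(none)) {
    sub <- mat[, none, drop = FALSE]
    chars <- setdiff(sort(unique(as.vector(sub))), c("-", "A", "C", "G", "T"))
    bb <- character(length(none)); bn <- integer(length(none))
    for (b in chars) {
      cnt <- colSums(sub == b)
      upd <- cnt > bn
      bb[upd] <- b
      bn[upd] <- cnt[upd]
    }
    best[none] <- bb
    bestn[none] <- bn
  }
  drop <- gap > bestn | bestn == 0L
  best[drop] <- "-"
  best
}
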