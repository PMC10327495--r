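# Low-level sequence helpers shared across modules.

COMPLEMENT_FROM <- "ACGTMRWSYKVHDBNacgtmrwsykvhdbn"
COMPLEMENT_TO   <- "TGCAKYWSRMBDHVNtgcakywsrmbdhvn"

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented; anything else is preserved.
#'
#' @param seq A single nucleotide string.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  intToUtf8(rev(utf8ToInt(chartr(COMPLEMENT_FROM, COMPLEMENT_TO, seq))))
}

complement_chars <- function(x) {
  chartr(COMPLEMENT_FROM, COMPLEMENT_TO, x)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Generate a random nucleotide sequence
#'
#' Uniform A/C/G/T sequence, used for simulation ancestors and test
#' fixtures.  Uses the current RNG state.
#'
#' @param length Sequence length in bp.
#' @return A single uppercase string.
#' @export
random_sequence <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Read a multi-record FASTA file
#'
#' @param path File path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' Records are wrapped at 80 columns.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# 2-bit base codes; NA for anything not A/C/G/T -----------------------------

base_codes <- function(seq) {
  codes <- rep(NA_integer_, 256L)
  codes[utf8ToInt("A")] <- 0L; codes[utf8ToInt("a")] <- 0L
  codes[utf8ToInt("C")] <- 1L; codes[utf8ToInt("c")] <- 1L
  codes[utf8ToInt("G")] <- 2L; codes[utf8ToInt("g")] <- 2L
  codes[utf8ToInt("T")] <- 3L; codes[utf8ToInt("t")] <- 3L
  codes[utf8ToInt(seq)]
}

# Encode every k-mer of seq as a base-4 integer held exactly in a double.
# Returns NA where the window contains a non-ACGT character.  k <= 26 keeps
# codes below 2^52 so all arithmetic is exact.
encode_kmers <- function(seq, k) {
  stopifnot(k >= 1L, k <= 26L)
  b <- base_codes(seq)
  L <- length(b)
  if (L < k) return(numeric(0))
  n <- L - k + 1L
  val <- numeric(n)
  bad <- integer(n)
  nab <- is.na(b)
  bnum <- as.numeric(b)
  bnum[nab] <- 0
  for (j in 0:(k - 1L)) {
    idx <- (1L + j):(n + j)
    val <- val * 4 + bnum[idx]
    bad <- bad + nab[idx]
  }
  val[bad > 0L] <- NA_real_
  val
}

# Codes of the reverse complement of each k-mer window (same indexing as
# encode_kmers).
encode_kmers_rc <- function(seq, k) {
  b <- base_codes(seq)
  L <- length(b)
  if (L < k) return(numeric(0))
  n <- L - k + 1L
  val <- numeric(n)
  bad <- integer(n)
  nab <- is.na(b)
  bnum <- 3 - as.numeric(b)
  bnum[nab] <- 0
  # reverse complement read right-to-left: most significant digit is the
  # complement of the last base in the window
  for (j in (k - 1L):0) {
    idx <- (1L + j):(n + j)
    val <- val * 4 + bnum[idx]
    bad <- bad + nab[idx]
  }
  val[bad > 0L] <- NA_real_
  val
}

canonical_kmer_codes <- function(seq, k) {
  pmin(encode_kmers(seq, k), encode_kmers_rc(seq, k))
}

decode_kmer <- function(code, k) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(code))
  rem <- code
  m <- matrix("", nrow = length(code), ncol = k)
  for (j in k:1) {
    d <- rem %% 4
    m[, j] <- bases[d + 1]
    rem <- (rem - d) / 4
  }
  apply(m, 1L, paste, collapse = "")
}

# 32-bit multiplicative hash (odd multiplier, hence invertible mod 2^32),
# computed exactly in doubles via a 16-bit split.
hash32 <- function(x) {
  a <- 2654435761
  a1 <- a %% 65536
  x1 <- floor(x / 65536) %% 65536
  x0 <- x %% 65536
  hi <- (a1 * x1) %% 65536
  (hi * 65536 + a * x0) %% 4294967296
}

# FNV-1a-style string hash used for deterministic block ids.
str_hash32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor on split 16-bit halves keeps everything in exact doubles
    h1 <- floor(h / 65536); h0 <- h %% 65536
    h0 <- bitwXor(as.integer(h0), b)
    h <- h1 * 65536 + h0
    # multiply by 16777619 mod 2^32
    m <- 16777619
    x1 <- floor(h / 65536) %% 65536
    x0 <- h %% 65536
    hi <- ((m %% 65536) * x1) %% 65536
    h <- (hi * 65536 + m * x0) %% 4294967296
  }
  h
}

hash_id <- function(...) {
  h <- str_hash32(paste(..., sep = "\x1f"))
  paste0(format(as.hexmode(floor(h / 65536)), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
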