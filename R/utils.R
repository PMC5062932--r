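# Shared low-level helpers: alphabet handling, k-mer extraction, seeds.

.datatable.aware <- TRUE

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Normalize a nucleotide string
#'
#' Uppercases and converts any character outside `A,C,G,T,N,-` (IUPAC
#' ambiguity codes, `?`, etc.) to `N`, with a warning when conversion occurs.
#'
#' @param x character vector of sequences.
#' @param warn warn when characters are converted.
#' @return character vector over `{A,C,G,T,N,-}`.
#' @export
normalize_sequence <- function(x, warn = TRUE) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN-]", x)
  if (any(bad)) {
    if (warn) warning(sum(bad), " sequence(s) contained non-ACGTN characters; converted to N")
    x[bad] <- gsub("[^ACGTN-]", "N", x[bad])
  }
  x
}

#' Reverse complement
#'
#' @param x character vector of DNA strings (may contain N and gaps).
#' @return reverse complement of each element.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of `seq` as a character vector (empty when too short).
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# Drop k-mers containing N (or gaps).
drop_ambiguous_kmers <- function(km) {
  km[!grepl("[N-]", km)]
}

#' Derive a stage-specific random seed from a run seed
#'
#' All randomness in the toolkit flows from one top-level seed through named
#' substreams, so each stage is independently reproducible. The derived seed
#' is a deterministic 31-bit mix of the run seed and the stream name.
#'
#' @param seed integer run seed.
#' @param stream character stream name, e.g. `"reads"`.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

# Gap-aware coordinate lift: position `pos` (0-based) in the ungapped row ->
# 0-based column in the gapped row. `pos` may equal the ungapped length
# (one-past-end), mapping to one past the last residue column.
lift_to_alignment <- function(gapped_row, pos) {
  chars <- strsplit(gapped_row, "")[[1]]
  residue_cols <- which(chars != "-") # 1-based columns carrying residues
  n_res <- length(residue_cols)
  vapply(pos, function(p) {
    if (p < 0 || p > n_res) stop("ungapped position out of range: ", p)
    if (p == n_res) {
      if (n_res == 0) return(0L) else return(residue_cols[n_res])
    }
    residue_cols[p + 1L] - 1L
  }, integer(1))
}

# Ungapped length of each element of a character vector of aligned rows.
ungapped_length <- function(x) nchar(gsub("-", "", x))

`%||%` <- function(a, b) if (is.null(a)) b else a
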