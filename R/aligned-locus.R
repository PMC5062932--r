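# AlignedLocus: one per-locus multiple sequence alignment with a per-cell
# mask. Internal coordinates are 0-based half-open throughout the package;
# on-disk reports are 1-based inclusive.

#' Construct an aligned locus
#'
#' @param locus_id locus identifier.
#' @param sequences named character vector of equal-length aligned rows
#'   (names = record ids), or a `seq_records` data.frame whose sequences are
#'   equal length.
#' @param taxa optional taxon label per row (defaults to [parse_taxon()] of
#'   the ids, or the records' `taxon` column).
#' @param mask optional logical matrix (rows x columns), `TRUE` = masked.
#' @param meta optional list of locus metadata (e.g. `anchor_center`,
#'   a 0-based column used for informativeness profiles).
#' @return an `aligned_locus` object with fields `locus_id`, `ids`, `taxa`,
#'   `seqs` (character matrix of single bases), `mask`, `meta`.
#' @export
aligned_locus <- function(locus_id, sequences, taxa = NULL, mask = NULL,
                          meta = list()) {
  if (inherits(sequences, "data.frame")) {
    taxa <- taxa %||% sequences$taxon
    ids <- sequences$id
    sequences <- setNames(sequences$sequence, ids)
  }
  ids <- names(sequences) %||% paste0("row", seq_along(sequences))
  sequences <- normalize_sequence(unname(sequences))
  widths <- nchar(sequences)
  if (length(sequences) == 0) stop("alignment has no rows")
  if (length(unique(widths)) != 1)
    stop("rows of locus '", locus_id, "' differ in length")
  taxa <- taxa %||% parse_taxon(ids)
  seqs <- do.call(rbind, strsplit(sequences, ""))
  rownames(seqs) <- ids
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(seqs), ncol(seqs))
  } else {
    stopifnot(identical(dim(mask), dim(seqs)))
  }
  structure(list(locus_id = locus_id, ids = ids, taxa = taxa,
                 seqs = seqs, mask = mask, meta = meta),
            class = "aligned_locus")
}

#' @export
print.aligned_locus <- function(x, ...) {
  cat("<aligned_locus> ", x$locus_id, ": ", nrow(x$seqs), " rows x ",
      ncol(x$seqs), " columns; ", sum(x$mask), " masked cell(s)\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param locus an `aligned_locus`.
#' @return integer column count.
#' @export
n_cols <- function(locus) ncol(locus$seqs)

#' Number of alignment rows
#' @param locus an `aligned_locus`.
#' @return integer row count.
#' @export
n_rows <- function(locus) nrow(locus$seqs)

#' Aligned rows as strings
#' @param locus an `aligned_locus`.
#' @param masked_as character used for masked cells (`NULL` keeps the base).
#' @return named character vector of rows.
#' @export
locus_strings <- function(locus, masked_as = NULL) {
  m <- locus$seqs
  if (!is.null(masked_as)) m[locus$mask] <- masked_as
  setNames(apply(m, 1, paste, collapse = ""), locus$ids)
}

#' Extract a column interval as a new locus
#' @param locus an `aligned_locus`.
#' @param start,end 0-based half-open column interval.
#' @param locus_id id for the child (default parent's id).
#' @return an `aligned_locus` over columns `[start, end)`.
#' @export
locus_slice <- function(locus, start, end, locus_id = locus$locus_id) {
  stopifnot(start >= 0, end <= n_cols(locus), start < end)
  cols <- seq(start + 1L, end)
  out <- locus
  out$locus_id <- locus_id
  out$seqs <- locus$seqs[, cols, drop = FALSE]
  out$mask <- locus$mask[, cols, drop = FALSE]
  out
}

#' Convert records to a locus, requiring equal lengths
#' @param records `seq_records` with equal-length sequences.
#' @param locus_id locus identifier.
#' @return an `aligned_locus`.
#' @export
as_aligned_locus <- function(records, locus_id) aligned_locus(locus_id, records)

#' Read one aligned locus from a FASTA file
#' @param path aligned FASTA (equal-length rows).
#' @param locus_id defaults to the file name without extension.
#' @param sample_map optional sample-to-taxon map.
#' @return an `aligned_locus`.
#' @export
read_aligned_fasta <- function(path, locus_id = NULL, sample_map = NULL) {
  locus_id <- locus_id %||% sub("\\.[^.]*$", "", basename(path))
  aligned_locus(locus_id, read_fasta(path, sample_map = sample_map))
}

#' Write an aligned locus to FASTA
#' @param locus an `aligned_locus`.
#' @param path output file.
#' @param masked_as symbol written for masked cells (default `"N"`).
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(locus, path, masked_as = "N") {
  s <- locus_strings(locus, masked_as = masked_as)
  write_fasta(seq_records(names(s), s, taxon = locus$taxa), path)
}
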