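# Relaxed PHYLIP + RAxML-style partition output for supermatrices.

#' Partition table for a set of loci
#'
#' Computes the contiguous 1-based inclusive column blocks each locus
#' occupies in a concatenation, in locus order.
#'
#' @param widths named integer vector of locus widths (names = locus ids).
#' @return data.frame with columns `locus_id`, `start`, `end` tiling
#'   `[1, sum(widths)]` exactly.
#' @export
partition_table <- function(widths) {
  stopifnot(length(widths) >= 1, all(widths >= 1))
  end <- cumsum(as.integer(widths))
  start <- c(1L, head(end, -1) + 1L)
  data.frame(locus_id = names(widths) %||% paste0("locus", seq_along(widths)),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Write a supermatrix as relaxed PHYLIP plus a partition file
#'
#' Emits `<base_path>.phy` (relaxed PHYLIP: names padded with spaces, full
#' sequence on one line) and `<base_path>.partitions` with one RAxML-style
#' line per locus: `DNA, <locus_id> = <start>-<end>` (1-based inclusive).
#'
#' @param matrix a `supermatrix` from [concatenate()].
#' @param base_path output path prefix.
#' @return character vector of the two file paths, invisibly.
#' @export
write_phylip_and_partitions <- function(matrix, base_path) {
  stopifnot(inherits(matrix, "supermatrix"))
  taxa <- matrix$taxa
  if (anyDuplicated(taxa)) stop("duplicate taxon labels in supermatrix")
  seqs <- apply(matrix$mat, 1, paste, collapse = "")
  phy <- paste0(base_path, ".phy")
  part <- paste0(base_path, ".partitions")
  pad <- max(nchar(taxa)) + 2L
  con <- file(phy, "w")
  writeLines(sprintf("%d %d", length(taxa), ncol(matrix$mat)), con)
  writeLines(sprintf("%-*s%s", pad, taxa, seqs), con)
  close(con)
  p <- matrix$partitions
  writeLines(sprintf("DNA, %s = %d-%d", p$locus_id, p$start, p$end), part)
  invisible(c(phy, part))
}
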