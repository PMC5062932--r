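# High-copy-region detection: a k-mer database built from probe-region
# alignments (observed k-mers plus all Hamming-distance-1 neighbors) is
# scanned against genomes; hit counts are tallied back onto alignment
# columns and over-threshold columns are masked before probe tiling.

#' Build the probe-region k-mer database
#'
#' For every ungapped k-mer of every row of every alignment, the k-mer and
#' (when `neighbors = 1`) all `3k` single-substitution variants are mapped to
#' the alignment column of the k-mer's first base. K-mers containing `N` are
#' not entered.
#'
#' @param alignments list of `aligned_locus`.
#' @param k k-mer length (default 15).
#' @param neighbors 0 (observed k-mers only) or 1 (add Hamming-distance-1
#'   substitution variants).
#' @return a `data.table` (`kmer`, `locus_id`, `column`) with 0-based
#'   columns, deduplicated per (kmer, locus, column); attribute `k`.
#' @export
build_kmer_db <- function(alignments, k = 15, neighbors = 1) {
  stopifnot(k >= 1, neighbors %in% c(0, 1))
  parts <- list()
  for (locus in alignments) {
    for (r in seq_len(n_rows(locus))) {
      chars <- locus$seqs[r, ]
      res_cols <- which(chars != "-")
      useq <- paste(chars[res_cols], collapse = "")
      if (nchar(useq) < k) next
      km <- kmers_of(useq, k)
      cols0 <- res_cols[seq_along(km)] - 1L
      ok <- !grepl("N", km, fixed = TRUE)
      if (!any(ok)) next
      km <- km[ok]; cols0 <- cols0[ok]
      all_km <- km; all_cols <- cols0
      if (neighbors == 1) {
        for (p in seq_len(k)) {
          cur <- substr(km, p, p)
          for (b in c("A", "C", "G", "T")) {
            differ <- cur != b
            if (!any(differ)) next
            variant <- paste0(substr(km[differ], 1, p - 1L), b,
                              substr(km[differ], p + 1L, k))
            all_km <- c(all_km, variant)
            all_cols <- c(all_cols, cols0[differ])
          }
        }
      }
      parts[[length(parts) + 1L]] <-
        data.table::data.table(kmer = all_km, locus_id = locus$locus_id,
                               column = all_cols)
    }
  }
  db <- if (length(parts)) unique(data.table::rbindlist(parts))
        else data.table::data.table(kmer = character(0),
                                    locus_id = character(0),
                                    column = integer(0))
  data.table::setattr(db, "k", as.integer(k))
  db[]
}

#' Tally genome occurrences of database k-mers onto alignment columns
#'
#' Slides a k-window over both strands of the genome; every exact database
#' hit increments the tally at each (locus, column) the k-mer maps to.
#' Windows containing `N` never hit.
#'
#' @param db database from [build_kmer_db()].
#' @param genome genome sequence (single-row `seq_records` or string).
#' @param genome_id label recorded in the tally.
#' @return a data.frame (`genome_id`, `locus_id`, `column`, `count`) with
#'   only nonzero-count rows.
#' @export
tally_genome <- function(db, genome, genome_id = "genome") {
  k <- attr(db, "k")
  gseq <- if (is.data.frame(genome)) genome$sequence[1] else normalize_sequence(genome)
  # database k-mers are N-free, so N-containing genome windows can never hit
  # and need no explicit filtering
  gkm <- c(kmers_of(gseq, k), kmers_of(revcomp(gseq), k))
  gkm <- gkm[gkm %in% db$kmer]
  if (length(gkm) == 0 || nrow(db) == 0)
    return(data.frame(genome_id = character(0), locus_id = character(0),
                      column = integer(0), count = integer(0)))
  counts <- data.table::data.table(kmer = gkm)[, list(n = .N), by = "kmer"]
  hits <- merge(db, counts, by = "kmer")
  if (nrow(hits) == 0)
    return(data.frame(genome_id = character(0), locus_id = character(0),
                      column = integer(0), count = integer(0)))
  tal <- hits[, list(count = sum(n)), by = c("locus_id", "column")]
  out <- as.data.frame(tal)
  out <- data.frame(genome_id = genome_id, out, stringsAsFactors = FALSE)
  out[order(out$locus_id, out$column), , drop = FALSE]
}

#' Mask high-copy alignment columns
#'
#' Any column whose tally exceeds `threshold` (strict `>`) in any genome is
#' masked in all rows. Bases are preserved; only the mask state changes.
#'
#' @param locus an `aligned_locus`.
#' @param tallies data.frame(s) from [tally_genome()] (rows for other loci
#'   are ignored); pass a list to combine several genomes.
#' @param threshold count threshold (default 100000, matching high-copy
#'   detection against Gb-scale genomes).
#' @return the locus with over-threshold columns masked.
#' @export
mask_high_copy <- function(locus, tallies, threshold = 100000) {
  if (is.data.frame(tallies)) tallies <- list(tallies)
  tal <- do.call(rbind, tallies)
  tal <- tal[tal$locus_id == locus$locus_id & tal$count > threshold, , drop = FALSE]
  if (nrow(tal) > 0) {
    cols <- unique(tal$column) + 1L
    locus$mask[, cols] <- TRUE
  }
  locus
}
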