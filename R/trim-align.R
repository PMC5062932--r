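# Alignment trimming/masking: three-rule procedure — flag good sites by
# column similarity, mask low-quality sliding windows, drop sparse columns.

#' Flag good alignment columns by similarity
#'
#' The similarity of a column is the fraction of its non-gap characters that
#' equal the modal non-gap base. A column is good iff similarity is strictly
#' greater than `min_similarity` and at least two non-gap characters are
#' present; all-gap columns are never good.
#'
#' @param locus an `aligned_locus` with at least 2 rows.
#' @param min_similarity similarity threshold, strict `>` (default 0.70).
#' @return `list(locus_id, good, unmasked_count)` — per-column logical and
#'   the count of unmasked non-gap characters.
#' @export
good_sites <- function(locus, min_similarity = 0.70) {
  if (n_rows(locus) < 2) stop("good_sites needs >= 2 rows")
  m <- locus$seqs
  good <- logical(ncol(m))
  for (cidx in seq_len(ncol(m))) {
    col <- m[, cidx]
    bases <- col[col != "-" & col != "N"]
    if (length(bases) >= 2) {
      sim <- max(table(bases)) / length(bases)
      good[cidx] <- sim > min_similarity
    }
  }
  unmasked <- colSums(locus$seqs != "-" & locus$seqs != "N" & !locus$mask)
  list(locus_id = locus$locus_id, good = good, unmasked_count = unmasked)
}

#' Mask low-quality alignment windows
#'
#' Every sliding window of `window` columns (step 1) containing fewer than
#' `min_good` good columns is masked across all rows; a column is masked
#' when any covering window triggers.
#'
#' @param locus an `aligned_locus`.
#' @param quality result of [good_sites()] (recomputed when `NULL`).
#' @param window window width in columns (default 20); an alignment
#'   narrower than `window` is evaluated as a single window.
#' @param min_good minimum good columns per window, strict `<` masks
#'   (default 10).
#' @param min_similarity forwarded to [good_sites()] when recomputing.
#' @return the locus with triggered columns masked in all rows.
#' @export
mask_low_quality <- function(locus, quality = NULL, window = 20,
                             min_good = 10, min_similarity = 0.70) {
  nc <- n_cols(locus)
  if (nc == 0) return(locus)
  if (is.null(quality)) quality <- good_sites(locus, min_similarity)
  good <- quality$good
  w <- min(window, nc)
  cg <- c(0L, cumsum(as.integer(good)))
  masked_cols <- logical(nc)
  for (s in seq_len(nc - w + 1L)) {
    if (cg[s + w] - cg[s] < min_good)
      masked_cols[seq(s, s + w - 1L)] <- TRUE
  }
  locus$mask[, masked_cols] <- TRUE
  locus
}

#' Drop sparse alignment columns
#'
#' Removes columns with fewer than `min_unmasked` unmasked non-gap
#' characters, preserving the order of the remaining columns.
#'
#' @param locus an `aligned_locus` (after masking).
#' @param min_unmasked minimum unmasked bases per retained column
#'   (default 10; strict: a column with exactly `min_unmasked` is kept).
#' @return the locus restricted to the retained columns.
#' @export
drop_sparse_columns <- function(locus, min_unmasked = 10) {
  unmasked <- colSums(locus$seqs != "-" & locus$seqs != "N" & !locus$mask)
  keep <- unmasked >= min_unmasked
  if (all(keep)) return(locus)
  out <- locus
  out$seqs <- locus$seqs[, keep, drop = FALSE]   # may legitimately be 0 columns
  out$mask <- locus$mask[, keep, drop = FALSE]
  out
}

#' Trim one alignment with the full three-rule procedure
#'
#' Runs [good_sites()], [mask_low_quality()] and [drop_sparse_columns()] in
#' order. The pipeline is idempotent: applying it twice equals applying it
#' once.
#'
#' @param locus an `aligned_locus`.
#' @param min_similarity column-similarity threshold (default 0.70).
#' @param window masking window width (default 20).
#' @param min_good minimum good columns per window (default 10).
#' @param min_unmasked minimum unmasked bases per retained column
#'   (default 10).
#' @return the trimmed `aligned_locus` (masked cells retained as mask state;
#'   written as `N` by [write_aligned_fasta()]).
#' @export
trim_alignment <- function(locus, min_similarity = 0.70, window = 20,
                           min_good = 10, min_unmasked = 10) {
  q <- good_sites(locus, min_similarity)
  masked <- mask_low_quality(locus, q, window = window, min_good = min_good)
  drop_sparse_columns(masked, min_unmasked = min_unmasked)
}
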