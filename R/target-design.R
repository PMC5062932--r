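# Target-locus selection: sliding-window pairwise identity over ortholog
# alignments and extraction of probe-ready regions.
#
# Pairwise identity ignores positions where either row carries a gap; pairs
# with no comparable position in a window are excluded from the mean.

# Per-pair match/comparable indicator vectors for all unordered row pairs.
# Returns list(match = P x C matrix, comp = P x C matrix) of 0/1.
pair_indicators <- function(locus) {
  m <- locus$seqs
  n <- nrow(m)
  pairs <- utils::combn(n, 2)
  ng <- m != "-"
  match_rows <- matrix(0L, ncol(pairs), ncol(m))
  comp_rows <- matrix(0L, ncol(pairs), ncol(m))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    comp <- ng[i, ] & ng[j, ]
    comp_rows[p, ] <- as.integer(comp)
    match_rows[p, ] <- as.integer(comp & m[i, ] == m[j, ])
  }
  list(match = match_rows, comp = comp_rows)
}

#' Mean pairwise identity of one alignment window
#'
#' Identity of a row pair = matching non-gap positions / positions where both
#' rows are non-gap; the window score is the mean over all unordered pairs,
#' excluding pairs with no comparable position.
#'
#' @param locus an `aligned_locus` with at least 2 rows.
#' @param start 0-based first column of the window.
#' @param width window width in columns (default 120).
#' @return a one-row data.frame (`locus_id`, `start`, `width`,
#'   `mean_pairwise_identity`); identity is `NaN` when no pair is comparable.
#' @export
window_identity <- function(locus, start, width = 120) {
  if (n_rows(locus) < 2) stop("window_identity needs >= 2 rows")
  if (start < 0 || start + width > n_cols(locus))
    stop("window [", start, ", ", start + width, ") outside alignment")
  ind <- pair_indicators(locus)
  cols <- seq(start + 1L, start + width)
  matches <- rowSums(ind$match[, cols, drop = FALSE])
  comps <- rowSums(ind$comp[, cols, drop = FALSE])
  ok <- comps > 0
  mpi <- if (any(ok)) mean(matches[ok] / comps[ok]) else NaN
  data.frame(locus_id = locus$locus_id, start = start, width = width,
             mean_pairwise_identity = mpi, stringsAsFactors = FALSE)
}

# Sliding-window (step 1) identity for all start positions, via cumulative
# sums of the per-pair indicators. Returns numeric vector indexed by
# 0-based start (NaN where no pair comparable).
all_window_identities <- function(locus, width = 120) {
  if (n_cols(locus) < width) return(numeric(0))
  ind <- pair_indicators(locus)
  cm <- cbind(0L, t(apply(ind$match, 1, cumsum)))
  cc <- cbind(0L, t(apply(ind$comp, 1, cumsum)))
  starts <- seq_len(n_cols(locus) - width + 1L)
  vapply(starts, function(s) {
    matches <- cm[, s + width] - cm[, s]
    comps <- cc[, s + width] - cc[, s]
    ok <- comps > 0
    if (any(ok)) mean(matches[ok] / comps[ok]) else NaN
  }, numeric(1))
}

#' Filter ortholog alignments by taxon count and window identity
#'
#' Keeps a locus iff it has at least `min_taxa` rows and some sliding
#' `window`-column region (step 1) has mean pairwise identity strictly
#' greater than `min_identity`.
#'
#' @param loci list of `aligned_locus`.
#' @param min_taxa minimum row count (default 6).
#' @param window window width in columns (default 120).
#' @param min_identity identity threshold, strict `>` (default 0.5).
#' @return the kept subset of `loci`.
#' @export
filter_ortholog_alignments <- function(loci, min_taxa = 6, window = 120,
                                       min_identity = 0.5) {
  keep <- vapply(loci, function(lc) {
    if (n_rows(lc) < min_taxa) return(FALSE)
    if (n_cols(lc) < window) return(FALSE)
    ident <- all_window_identities(lc, width = window)
    any(!is.nan(ident) & ident > min_identity)
  }, logical(1))
  loci[keep]
}

#' Select preliminary target regions
#'
#' Returns the maximal column intervals of the alignment that (A) are at
#' least `min_len` columns long, (B) contain no exon boundary, and (C)
#' contain no gap character in any retained row. Rows consisting entirely of
#' gaps/missing data are dropped before the scan.
#'
#' @param locus an `aligned_locus`.
#' @param boundaries integer vector of exon cut points in 0-based alignment
#'   coordinates (a boundary at `b` separates columns `b-1` and `b`).
#' @param min_len minimum region width (default 150).
#' @return data.frame with columns `locus_id`, `start`, `end` (0-based
#'   half-open), `length`, `mean_pairwise_identity`.
#' @export
select_preliminary_targets <- function(locus, boundaries = integer(0),
                                       min_len = 150) {
  live <- apply(locus$seqs, 1, function(r) any(r != "-" & r != "N"))
  if (!any(live)) return(target_region_frame())
  seqs <- locus$seqs[live, , drop = FALSE]
  nc <- ncol(seqs)
  gap_col <- apply(seqs == "-", 2, any)
  # blocked "edges": a boundary at b forbids an interval crossing b
  regions <- list()
  cuts <- sort(unique(c(0L, as.integer(boundaries), nc)))
  for (ci in seq_len(length(cuts) - 1L)) {
    lo <- cuts[ci]; hi <- cuts[ci + 1L]
    # maximal gap-free runs within [lo, hi)
    ok <- !gap_col[seq(lo + 1L, hi)]
    r <- rle(ok)
    pos <- lo + c(0L, cumsum(r$lengths))
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= min_len)
        regions[[length(regions) + 1L]] <- c(pos[k], pos[k] + r$lengths[k])
    }
  }
  if (length(regions) == 0) return(target_region_frame())
  sub <- locus
  sub$seqs <- seqs
  sub$mask <- locus$mask[live, , drop = FALSE]
  out <- do.call(rbind, lapply(regions, function(iv) {
    mpi <- if (nrow(seqs) >= 2)
      window_identity(sub, iv[1], iv[2] - iv[1])$mean_pairwise_identity
    else NA_real_
    data.frame(locus_id = locus$locus_id, start = iv[1], end = iv[2],
               length = iv[2] - iv[1], mean_pairwise_identity = mpi,
               stringsAsFactors = FALSE)
  }))
  out
}

target_region_frame <- function() {
  data.frame(locus_id = character(0), start = integer(0), end = integer(0),
             length = integer(0), mean_pairwise_identity = numeric(0),
             stringsAsFactors = FALSE)
}

#' Per-species ungapped sequences of a target region
#'
#' @param locus the `aligned_locus` the region was selected from.
#' @param start,end 0-based half-open column interval.
#' @return named character vector (names = row ids) of ungapped sequences;
#'   rows with no residue in the interval are dropped.
#' @export
target_sequences <- function(locus, start, end) {
  s <- locus_strings(locus_slice(locus, start, end))
  s <- gsub("-", "", s)
  s[nchar(s) > 0]
}

#' Split an alignment at exon boundaries
#'
#' @param locus an `aligned_locus`.
#' @param boundaries 0-based cut points, each strictly inside `(0, n_cols)`.
#' @return list of child `aligned_locus` whose column blocks partition the
#'   parent in order; ids suffixed `_e1`, `_e2`, ...
#' @export
split_alignment_at_boundaries <- function(locus, boundaries) {
  nc <- n_cols(locus)
  boundaries <- sort(unique(as.integer(boundaries)))
  if (any(boundaries <= 0 | boundaries >= nc))
    stop("boundary outside (0, ", nc, ")")
  cuts <- c(0L, boundaries, nc)
  lapply(seq_len(length(cuts) - 1L), function(i) {
    locus_slice(locus, cuts[i], cuts[i + 1L],
                locus_id = paste0(locus$locus_id, "_e", i))
  })
}
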