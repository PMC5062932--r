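# Exon-boundary detection: (1) exact k-mer chaining of a transcript against
# a genome; (2) read-mapping discordance around splice junctions.

exon_map <- function(transcript_id, boundaries, evidence, blocks = NULL) {
  structure(list(transcript_id = transcript_id,
                 boundaries = sort(unique(as.integer(boundaries))),
                 evidence = evidence, blocks = blocks),
            class = "exon_map")
}

#' @export
print.exon_map <- function(x, ...) {
  cat("<exon_map> ", x$transcript_id, " (", x$evidence, "): ",
      length(x$boundaries), " boundary/ies",
      if (length(x$boundaries)) paste0(" at ", paste(x$boundaries, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

# Maximal same-offset match blocks of transcript k-mers against one genome
# strand. Returns data.frame(t_start, t_end, g_start, g_end) 0-based
# half-open in transcript/strand coordinates. Seeds placed at more than
# `max_hits` genome positions (k-mers inside high-copy repeats) carry no
# placement information and are skipped, as in standard seed-and-chain
# mappers; without the cap a repeat-spanning transcript can seed O(repeat
# length) diagonals and stall the chaining DP.
match_blocks <- function(transcript, genome_seq, k, gk = NULL,
                         max_hits = 64L) {
  L <- nchar(transcript)
  tk <- kmers_of(transcript, k)
  if (is.null(gk)) gk <- kmers_of(genome_seq, k)
  valid_t <- !grepl("[N-]", tk)
  if (!any(valid_t)) return(NULL)
  # N-containing genome windows can never equal a valid transcript k-mer,
  # so only genome positions carrying a transcript k-mer need indexing
  sel <- which(gk %in% tk[valid_t])
  if (length(sel) == 0) return(NULL)
  gi <- split(sel - 1L, gk[sel]) # kmer -> 0-based genome starts
  gi <- gi[lengths(gi) <= max_hits]
  if (length(gi) == 0) return(NULL)
  idx <- which(valid_t)
  g_per_t <- gi[match(tk[idx], names(gi))]
  n_hits <- lengths(g_per_t) # 0 where the k-mer is absent or repetitive
  hits_t <- rep(idx - 1L, n_hits)
  hits_g <- unlist(g_per_t, use.names = FALSE)
  if (length(hits_t) == 0) return(NULL)
  by_off <- split(hits_t, hits_g - hits_t)
  out <- list()
  for (oi in seq_along(by_off)) {
    o <- as.integer(names(by_off)[oi])
    ts <- sort(by_off[[oi]])
    for (run in split(ts, cumsum(c(1L, diff(ts) != 1L)))) {
      out[[length(out) + 1L]] <-
        data.frame(t_start = run[1], t_end = run[length(run)] + k,
                   g_start = run[1] + o, g_end = run[length(run)] + k + o)
    }
  }
  blocks <- do.call(rbind, out)
  blocks[order(blocks$t_start, blocks$g_start), , drop = FALSE]
}

# Colinear chain of blocks maximizing transcript coverage (O(B^2) DP).
# Blocks may overlap by up to `slack` transcript bases: junction-flanking
# bases that coincide with intron edges extend a block past the true splice
# point by a few bases (P(extension >= e) = 4^-e per side).
chain_blocks <- function(blocks, slack = 0L) {
  if (is.null(blocks) || nrow(blocks) == 0) return(NULL)
  n <- nrow(blocks)
  cov <- blocks$t_end - blocks$t_start
  best <- cov
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1)) {
      overlap <- max(0L, blocks$t_end[i] - blocks$t_start[j])
      if (blocks$t_start[j] >= blocks$t_end[i] - slack &&
          blocks$g_start[j] >= blocks$g_end[i] - slack &&
          best[i] + cov[j] - overlap > best[j]) {
        best[j] <- best[i] + cov[j] - overlap
        prev[j] <- i
      }
    }
  }
  path <- integer(0)
  j <- which.max(best)
  while (!is.na(j)) { path <- c(j, path); j <- prev[j] }
  blocks[path, , drop = FALSE]
}

#' Map exon boundaries by exact k-mer chaining against a genome
#'
#' Exact transcript k-mers are located on both genome strands, grouped into
#' maximal same-diagonal blocks, and chained colinearly (the strand with the
#' larger chained transcript coverage wins). A boundary is reported at each
#' transcript position where consecutive chained blocks are adjacent in the
#' transcript but separated by more than zero bases (an intron) in the
#' genome. K-mers containing `N` never match; k-mers occurring at more than
#' `max_hits` genome positions (seeds inside high-copy repeats) carry no
#' placement information and are skipped, as in standard seed-and-chain
#' mappers.
#'
#' @param transcript a single-row `seq_records` data.frame (or character
#'   string) for the transcript.
#' @param genome the genome sequence (single-row `seq_records` or string).
#' @param k k-mer length (default 40).
#' @param genome_kmers optional precomputed k-mer vectors of the genome,
#'   `list(fwd = , rev = )` from [genome_kmer_cache()]; avoids rescanning
#'   the genome when mapping many transcripts against it.
#' @param max_hits maximum genome placements per seed k-mer (default 64);
#'   more repetitive seeds are skipped.
#' @return an `exon_map` with 0-based transcript cut points and
#'   `evidence = "genome_kmer"`; empty (with a warning) when no block is
#'   found.
#' @export
map_exons_by_kmer <- function(transcript, genome, k = 40, genome_kmers = NULL,
                              max_hits = 64L) {
  tid <- if (is.data.frame(transcript)) transcript$id[1] else "transcript"
  tseq <- if (is.data.frame(transcript)) transcript$sequence[1] else normalize_sequence(transcript)
  gseq <- if (is.data.frame(genome)) genome$sequence[1] else normalize_sequence(genome)
  if (k > nchar(tseq)) stop("k exceeds transcript length")
  slack <- min(k - 1L, 5L)
  fwd <- chain_blocks(match_blocks(tseq, gseq, k, gk = genome_kmers$fwd,
                                   max_hits = max_hits),
                      slack = slack)
  rev <- chain_blocks(match_blocks(tseq, revcomp(gseq), k,
                                   gk = genome_kmers$rev,
                                   max_hits = max_hits),
                      slack = slack)
  covered <- function(b) if (is.null(b)) 0L else sum(b$t_end - b$t_start)
  chain <- if (covered(fwd) >= covered(rev)) fwd else rev
  if (is.null(chain) || nrow(chain) == 0) {
    warning("no ", k, "-mer match block found for ", tid)
    return(exon_map(tid, integer(0), "genome_kmer"))
  }
  boundaries <- integer(0)
  if (nrow(chain) > 1) {
    for (i in seq_len(nrow(chain) - 1L)) {
      gap_t <- chain$t_start[i + 1L] - chain$t_end[i]
      intron_len <- (chain$g_start[i + 1L] - chain$g_end[i]) - gap_t
      # adjacent (or overlapping by junction coincidence) in the transcript,
      # separated in the genome -> splice point at the left block's end
      if (gap_t <= 0 && intron_len > 0)
        boundaries <- c(boundaries, chain$t_end[i])
    }
  }
  exon_map(tid, boundaries, "genome_kmer", blocks = chain)
}

#' Precompute the k-mer vectors of a genome (both strands)
#'
#' @param genome single-row `seq_records` or string.
#' @param k k-mer length.
#' @return `list(fwd, rev)` of k-mer character vectors, for the
#'   `genome_kmers` argument of [map_exons_by_kmer()].
#' @export
genome_kmer_cache <- function(genome, k = 40) {
  gseq <- if (is.data.frame(genome)) genome$sequence[1] else normalize_sequence(genome)
  list(fwd = kmers_of(gseq, k), rev = kmers_of(revcomp(gseq), k))
}

# Default read placement: ungapped seed-and-extend against the transcript.
# Seeds of length `seed_k` are tried at several read offsets; the candidate
# (strand, offset) minimizing the mismatch count over the read/transcript
# overlap wins. Returns NULL or list(offset, mismatch = logical vector over
# covered transcript positions, t_lo, t_hi) with 0-based half-open [t_lo,t_hi).
place_read <- function(read_seq, transcript, seed_k = 12) {
  L <- nchar(transcript)
  tchars <- strsplit(transcript, "")[[1]]
  best <- NULL
  for (orient in c("fwd", "rev")) {
    rs <- if (orient == "fwd") read_seq else revcomp(read_seq)
    rl <- nchar(rs)
    if (rl < seed_k) next
    rchars <- strsplit(rs, "")[[1]]
    seed_starts <- unique(pmax(1L, floor(seq(1, rl - seed_k + 1, length.out = 4))))
    cands <- integer(0)
    for (ss in seed_starts) {
      seed <- substr(rs, ss, ss + seed_k - 1L)
      hits <- gregexpr(seed, transcript, fixed = TRUE)[[1]]
      if (hits[1] != -1) cands <- c(cands, hits - ss) # 0-based read offset
    }
    for (off in unique(cands)) {
      t_lo <- max(0L, off)
      t_hi <- min(L, off + rl)
      if (t_hi <= t_lo) next
      tpos <- seq(t_lo + 1L, t_hi)
      rpos <- tpos - off
      mm <- tchars[tpos] != rchars[rpos]
      if (is.null(best) || sum(mm) < best$n_mismatch) {
        best <- list(offset = off, mismatch = mm, t_lo = t_lo, t_hi = t_hi,
                     n_mismatch = sum(mm))
      }
    }
  }
  best
}

#' Map exon boundaries from read-mapping discordance
#'
#' Genomic reads crossing a splice junction match the transcript on one side
#' of the junction and mismatch heavily on the other (the intron). For each
#' transcript position `p`, reads whose placement spans `[p - flank,
#' p + flank)` are examined; `p` is a boundary candidate when at least
#' `min_reads` reads have per-base mismatch rate `<= mismatch_frac` on one
#' side of `p` and `> mismatch_frac` on the other. Runs of adjacent
#' candidates are merged to the position maximizing the summed side
#' contrast.
#'
#' @param transcript single-row `seq_records` or character string.
#' @param reads a `seq_records` data.frame of reads.
#' @param flank half-window examined on each side of a position (default 30).
#' @param mismatch_frac per-base mismatch-rate threshold (default 0.2).
#' @param min_reads minimum discordant reads to call a boundary (default 5).
#' @param aligner read-placement function with the contract of the internal
#'   seed-and-extend default (see Details in the package vignette).
#' @return an `exon_map` with `evidence = "read_discordance"`.
#' @export
map_exons_by_reads <- function(transcript, reads, flank = 30,
                               mismatch_frac = 0.2, min_reads = 5,
                               aligner = place_read) {
  tid <- if (is.data.frame(transcript)) transcript$id[1] else "transcript"
  tseq <- if (is.data.frame(transcript)) transcript$sequence[1] else normalize_sequence(transcript)
  L <- nchar(tseq)
  if (is.null(reads) || nrow(reads) == 0)
    return(exon_map(tid, integer(0), "read_discordance"))
  placements <- lapply(reads$sequence, aligner, transcript = tseq)
  placements <- placements[!vapply(placements, is.null, logical(1))]
  if (length(placements) == 0)
    return(exon_map(tid, integer(0), "read_discordance"))
  # cumulative mismatch count per read over transcript coordinates
  n_cand <- integer(L + 1L)      # candidates indexed by 0-based position p
  contrast <- numeric(L + 1L)
  for (p in seq(flank, L - flank)) {
    lo <- p - flank; hi <- p + flank
    votes <- 0L; csum <- 0
    for (pl in placements) {
      if (pl$t_lo > lo || pl$t_hi < hi) next
      idx_l <- seq(lo - pl$t_lo + 1L, p - pl$t_lo)
      idx_r <- seq(p - pl$t_lo + 1L, hi - pl$t_lo)
      rl <- mean(pl$mismatch[idx_l]); rr <- mean(pl$mismatch[idx_r])
      disc <- (rl <= mismatch_frac) != (rr <= mismatch_frac)
      if (disc) { votes <- votes + 1L; csum <- csum + abs(rl - rr) }
    }
    if (votes >= min_reads) {
      n_cand[p + 1L] <- votes
      contrast[p + 1L] <- csum
    }
  }
  cand <- which(n_cand > 0) - 1L
  if (length(cand) == 0) return(exon_map(tid, integer(0), "read_discordance"))
  runs <- split(cand, cumsum(c(1L, diff(cand) > 1L)))
  boundaries <- vapply(runs, function(run) {
    run[which.max(contrast[run + 1L])]
  }, numeric(1))
  exon_map(tid, boundaries, "read_discordance")
}
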