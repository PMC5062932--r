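# Fixture builders and independent brute-force oracles. Oracles are written
# as plain loops so they share no code path with the package functions they
# check.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# random alignment as an aligned_locus; gap_prob inserts gap characters
rand_locus <- function(n_rows, n_cols, gap_prob = 0, locus_id = "L1",
                       taxa = NULL) {
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(BASES, n_cols, replace = TRUE)
    if (gap_prob > 0) chars[runif(n_cols) < gap_prob] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  ids <- sprintf("t%02d", seq_len(n_rows))
  aligned_locus(locus_id, setNames(rows, ids),
                taxa = taxa %||% ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random seq_records with read support
rand_records <- function(n, len = 50, support = NULL) {
  seq_records(sprintf("r%03d", seq_len(n)),
              vapply(seq_len(n), function(i) rand_seq(len), character(1)),
              read_support = support %||% sample(0:100, n, replace = TRUE))
}

# gene with known exon/intron structure and identifiable junctions (the
# intron's first base differs from the next exon's first base and its last
# base differs from the previous exon's last base, so the planted cut point
# is the unique splice annotation consistent with the sequences)
make_gene <- function(exon_lens, intron_lens) {
  stopifnot(length(intron_lens) == length(exon_lens) - 1)
  exons <- lapply(exon_lens, function(n) strsplit(rand_seq(n), "")[[1]])
  introns <- lapply(seq_along(intron_lens), function(i) {
    chars <- strsplit(rand_seq(intron_lens[i]), "")[[1]]
    nxt <- exons[[i + 1]][1]
    prv <- exons[[i]][length(exons[[i]])]
    chars[1] <- sample(setdiff(BASES, nxt), 1)
    chars[length(chars)] <- sample(setdiff(BASES, prv), 1)
    chars
  })
  pieces <- character(0)
  for (i in seq_along(exons)) {
    pieces <- c(pieces, paste(exons[[i]], collapse = ""))
    if (i <= length(introns)) pieces <- c(pieces, paste(introns[[i]], collapse = ""))
  }
  list(transcript = paste(vapply(exons, paste, character(1), collapse = ""),
                          collapse = ""),
       genomic = paste(pieces, collapse = ""),
       boundaries = head(cumsum(exon_lens), -1))
}

# stack a simulated clade's copy-1 transcripts into per-locus alignments
# (the simulator emits no indels, so transcripts of a locus align as-is)
sim_ortholog_loci <- function(sim) {
  tb <- sim$truth$exon_boundaries
  lapply(sort(unique(tb$locus)), function(li) {
    rows <- tb[tb$locus == li & tb$copy == 1, ]
    seqs <- vapply(seq_len(nrow(rows)), function(i) {
      tr <- sim$transcriptomes[[rows$species[i]]]
      tr$sequence[tr$id == rows$transcript_id[i]]
    }, character(1))
    aligned_locus(sprintf("L%03d", li), setNames(seqs, rows$transcript_id),
                  taxa = rows$species)
  })
}

# consensus records annotated with their target locus
sim_consensus_with_locus <- function(sim, seed = NULL) {
  cs <- simulate_consensus_set(sim, seed = seed)
  recs <- cs$records
  recs$locus <- cs$truth$locus[match(recs$id, cs$truth$id)]
  list(records = recs, truth = cs$truth)
}

# ---- independent oracles ---------------------------------------------------

# mean pairwise identity of a window by direct double loop
oracle_window_identity <- function(locus, start, width) {
  m <- locus$seqs
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    match <- 0; comp <- 0
    for (cidx in seq(start + 1, start + width)) {
      a <- m[i, cidx]; b <- m[j, cidx]
      if (a != "-" && b != "-") {
        comp <- comp + 1
        if (a == b) match <- match + 1
      }
    }
    if (comp > 0) vals <- c(vals, match / comp)
  }
  if (length(vals) == 0) NaN else mean(vals)
}

# brute-force genome tally: walk every window of both strands, look the
# k-mer up in a plain list built from the db rows
oracle_tally <- function(db, genome, k) {
  lookup <- list()
  for (i in seq_len(nrow(db))) {
    key <- db$kmer[i]
    lookup[[key]] <- rbind(lookup[[key]],
                           data.frame(locus_id = db$locus_id[i],
                                      column = db$column[i]))
  }
  counts <- list()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  for (strand_seq in c(genome, rc)) {
    for (pos in seq_len(nchar(strand_seq) - k + 1)) {
      w <- substr(strand_seq, pos, pos + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      ent <- lookup[[w]]
      if (is.null(ent)) next
      for (r in seq_len(nrow(ent))) {
        key <- paste(ent$locus_id[r], ent$column[r], sep = "\r")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  counts
}

# k-mer profile + Jaccard distance by direct enumeration
oracle_profile <- function(seq, k) {
  out <- character(0)
  n <- nchar(seq)
  for (p in seq_len(max(0, n - k + 1))) {
    w <- substr(seq, p, p + k - 1)
    if (!grepl("[N-]", w)) out <- c(out, w)
  }
  span <- 3 * (k - 1) + 1
  if (n >= span) {
    chars <- strsplit(seq, "")[[1]]
    for (p in seq_len(n - span + 1)) {
      w <- paste(chars[seq(p, by = 3, length.out = k)], collapse = "")
      if (!grepl("[N-]", w)) out <- c(out, w)
    }
  }
  unique(out)
}

oracle_distance <- function(a, b, k) {
  pa <- oracle_profile(a, k); pb <- oracle_profile(b, k)
  if (length(pa) == 0 && length(pb) == 0) return(1)
  1 - length(intersect(pa, pb)) / length(union(pa, pb))
}

# per-column variable/informative tally by direct loops
oracle_site_classes <- function(mat) {
  nv <- 0L; ni <- 0L
  for (cidx in seq_len(ncol(mat))) {
    col <- mat[, cidx]
    col <- col[!(col %in% c("-", "N", "?"))]
    if (length(col) == 0) next
    tab <- table(col)
    if (length(tab) >= 2) nv <- nv + 1L
    if (sum(tab >= 2) >= 2) ni <- ni + 1L
  }
  c(nv, ni)
}

# columns masked by the trim window rule, by direct scan
oracle_trim_mask <- function(good, window, min_good) {
  nc <- length(good)
  w <- min(window, nc)
  masked <- rep(FALSE, nc)
  for (s in seq_len(nc - w + 1)) {
    cnt <- sum(good[s:(s + w - 1)])
    if (cnt < min_good) masked[s:(s + w - 1)] <- TRUE
  }
  masked
}

# naive species-constrained average linkage: recompute every cluster-pair
# distance from the raw matrix at every step
oracle_cluster <- function(records, dist) {
  clusters <- lapply(seq_len(nrow(records)), identity)
  repeat {
    if (length(clusters) < 2) break
    cand <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      if (length(intersect(records$taxon[clusters[[i]]],
                           records$taxon[clusters[[j]]])) > 0) next
      dsum <- 0; cnt <- 0
      for (a in clusters[[i]]) for (b in clusters[[j]]) {
        dsum <- dsum + dist[a, b]; cnt <- cnt + 1
      }
      d <- dsum / cnt
      lab <- sort(c(min(records$id[clusters[[i]]]),
                    min(records$id[clusters[[j]]])))
      better <- is.null(cand) || d < cand$d ||
        (d == cand$d && (lab[1] < cand$lab[1] ||
                         (lab[1] == cand$lab[1] && lab[2] < cand$lab[2])))
      if (better) cand <- list(i = i, j = j, d = d, lab = lab)
    }
    if (is.null(cand)) break
    clusters[[cand$i]] <- c(clusters[[cand$i]], clusters[[cand$j]])
    clusters[[cand$j]] <- NULL
  }
  out <- lapply(clusters, function(m) sort(records$id[m]))
  out[order(vapply(out, `[`, character(1), 1))]
}
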