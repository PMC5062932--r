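# Post-capture orthology: read-support filtering, 20-mer profile distances,
# and species-constrained average-linkage clustering of homologs.

#' Filter consensus sequences by supporting-read count
#'
#' Removes records derived from fewer than `min_reads` reads (strict:
#' a record with exactly `min_reads` is kept).
#'
#' @param records `seq_records` with `read_support` present on every row.
#' @param min_reads minimum supporting reads (default 35).
#' @return the kept records.
#' @export
filter_consensus <- function(records, min_reads = 35) {
  if (nrow(records) == 0) return(records)
  if (anyNA(records$read_support))
    stop("read_support missing for record(s): ",
         paste(records$id[is.na(records$read_support)], collapse = ", "))
  records[records$read_support >= min_reads, , drop = FALSE]
}

#' K-mer profile of a sequence
#'
#' The profile is the set union of all contiguous k-mers and all
#' every-third-position k-mers (bases at `p, p+3, ..., p+3(k-1)`; these
#' accommodate variable third codon positions in exonic sequence). K-mers
#' containing `N` are excluded; a sequence shorter than `k` yields an empty
#' profile.
#'
#' @param sequence character string (or single-row `seq_records`).
#' @param k k-mer length (default 20).
#' @return `list(k, kmers)` of class `kmer_profile`.
#' @export
kmer_profile <- function(sequence, k = 20) {
  seq <- if (is.data.frame(sequence)) sequence$sequence[1] else normalize_sequence(sequence)
  seq <- gsub("-", "", seq)
  n <- nchar(seq)
  contiguous <- drop_ambiguous_kmers(kmers_of(seq, k))
  strided <- character(0)
  span <- 3L * (k - 1L) + 1L   # bases spanned by a stride-3 k-mer
  if (n >= span) {
    chars <- strsplit(seq, "")[[1]]
    strided <- vapply(seq_len(n - span + 1L), function(p) {
      paste(chars[seq(p, by = 3L, length.out = k)], collapse = "")
    }, character(1))
    strided <- drop_ambiguous_kmers(strided)
  }
  structure(list(k = as.integer(k), kmers = unique(c(contiguous, strided))),
            class = "kmer_profile")
}

#' K-mer set distance between two profiles
#'
#' Similarity is the fraction of k-mers observed in the two sequences that
#' are found in both (Jaccard: intersection over union); distance is one
#' minus the similarity. Two empty profiles give distance 1 with a warning.
#'
#' @param a,b `kmer_profile`s sharing `k`.
#' @param denominator `"union"` (Jaccard, default) or `"smaller"` (overlap
#'   coefficient denominator).
#' @return distance in `[0, 1]`.
#' @export
pair_distance <- function(a, b, denominator = c("union", "smaller")) {
  denominator <- match.arg(denominator)
  if (a$k != b$k) stop("profiles have different k (", a$k, " vs ", b$k, ")")
  if (length(a$kmers) == 0 && length(b$kmers) == 0) {
    warning("two empty k-mer profiles; distance set to 1")
    return(1)
  }
  inter <- length(intersect(a$kmers, b$kmers))
  denom <- if (denominator == "union") length(union(a$kmers, b$kmers))
           else max(1L, min(length(a$kmers), length(b$kmers)))
  1 - inter / denom
}

#' Pairwise k-mer distance matrix for a set of homologs
#'
#' @param records `seq_records`.
#' @param k k-mer length (default 20).
#' @param denominator see [pair_distance()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distance_matrix <- function(records, k = 20, denominator = "union") {
  n <- nrow(records)
  profiles <- lapply(records$sequence, kmer_profile, k = k)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <-
        suppressWarnings(pair_distance(profiles[[i]], profiles[[j]],
                                       denominator = denominator))
    }
  }
  d
}

#' Cluster homologs into species-constrained ortholog sets
#'
#' Agglomerative clustering with unweighted average linkage: at each step
#' the admissible pair of clusters with the minimum average pairwise
#' distance is merged, where a pair is admissible only if the union still
#' contains at most one sequence per taxon. Merging stops when no
#' admissible pair remains, or when the minimum admissible distance exceeds
#' `max_distance` (if set). Ties are broken toward the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' member id).
#'
#' For a gene duplication predating the clade root this splits homologs
#' into one ortholog set per copy; a duplication inside the clade yields
#' one full cluster plus a second cluster holding the descendants of the
#' duplication branch.
#'
#' @param records `seq_records` of homologs for one target locus.
#' @param k k-mer length for the distance (default 20).
#' @param max_distance optional merge cutoff (default: merge until the
#'   species constraint blocks).
#' @param denominator see [pair_distance()].
#' @param dist optional precomputed distance matrix (ids as dimnames).
#' @return list of clusters, each `list(cluster_id, members, species_set)`
#'   where `members` is a `seq_records` subset.
#' @export
cluster_orthologs <- function(records, k = 20, max_distance = NULL,
                              denominator = "union", dist = NULL) {
  n <- nrow(records)
  if (n == 0) return(list())
  if (is.null(dist)) dist <- distance_matrix(records, k = k,
                                             denominator = denominator)
  clusters <- lapply(seq_len(n), identity)  # member row indices
  repeat {
    if (length(clusters) < 2) break
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        taxa_i <- records$taxon[clusters[[i]]]
        taxa_j <- records$taxon[clusters[[j]]]
        if (length(intersect(taxa_i, taxa_j)) > 0) next
        d <- mean(dist[clusters[[i]], clusters[[j]]])
        lab <- sort(c(min(records$id[clusters[[i]]]),
                      min(records$id[clusters[[j]]])))
        if (is.null(best) || d < best$d ||
            (d == best$d && (lab[1] < best$lab[1] ||
                             (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = d, lab = lab)
        }
      }
    }
    if (is.null(best)) break
    if (!is.null(max_distance) && best$d > max_distance) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  # deterministic output order: by smallest member id
  ord <- order(vapply(clusters, function(m) min(records$id[m]), character(1)))
  clusters <- clusters[ord]
  lapply(seq_along(clusters), function(ci) {
    m <- clusters[[ci]][order(records$id[clusters[[ci]]])]
    list(cluster_id = ci, members = records[m, , drop = FALSE],
         species_set = sort(unique(records$taxon[m])))
  })
}

#' Filter ortholog clusters by taxon occupancy
#'
#' Keeps clusters whose species count is at least `min_fraction` of the
#' total (a cluster at exactly the threshold is kept; removal applies to
#' clusters with strictly fewer species).
#'
#' @param clusters list from [cluster_orthologs()].
#' @param n_species_total number of species in the study.
#' @param min_fraction occupancy threshold (default 0.75).
#' @return the kept clusters.
#' @export
filter_clusters <- function(clusters, n_species_total, min_fraction = 0.75) {
  stopifnot(n_species_total >= 1)
  keep <- vapply(clusters, function(cl) {
    length(cl$species_set) / n_species_total >= min_fraction
  }, logical(1))
  clusters[keep]
}
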