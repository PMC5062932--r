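# Probe tiling at fixed density and replication of the probe set up to the
# enrichment-kit capacity.

#' Tile capture probes across a reference sequence
#'
#' Probes of `probe_len` bases are placed every `round(probe_len / density)`
#' bases starting at 0; the final probe is shifted left so it ends exactly
#' at the sequence end. Probes overlapping any masked base are discarded.
#' Sequences shorter than `probe_len` yield no probes.
#'
#' @param sequence ungapped reference sequence (string).
#' @param mask logical vector (length = `nchar(sequence)`), `TRUE` = masked.
#' @param probe_len probe length in bases (default 120).
#' @param density tiling density: mean probes covering an interior base
#'   (default 4.0, i.e. a 30-base step for 120-base probes).
#' @param locus_id,reference_taxon labels carried onto the probes.
#' @return data.frame (`probe_id`, `locus_id`, `reference_taxon`, `start`
#'   (0-based), `sequence`, `replicates = 1`).
#' @export
tile_probes <- function(sequence, mask = NULL, probe_len = 120, density = 4.0,
                        locus_id = "locus", reference_taxon = "ref") {
  stopifnot(density > 0)
  L <- nchar(sequence)
  if (is.null(mask)) mask <- rep(FALSE, L)
  stopifnot(length(mask) == L)
  if (L < probe_len) return(probe_frame())
  spacing <- max(1L, as.integer(round(probe_len / density)))
  starts <- seq(0L, L - probe_len, by = spacing)
  if (starts[length(starts)] != L - probe_len)
    starts <- c(starts, L - probe_len)
  keep <- vapply(starts, function(s) !any(mask[seq(s + 1L, s + probe_len)]),
                 logical(1))
  starts <- starts[keep]
  if (length(starts) == 0) return(probe_frame())
  data.frame(probe_id = sprintf("%s|%s|%d", locus_id, reference_taxon, starts),
             locus_id = locus_id, reference_taxon = reference_taxon,
             start = starts,
             sequence = substring(sequence, starts + 1L, starts + probe_len),
             replicates = 1L, stringsAsFactors = FALSE)
}

probe_frame <- function() {
  data.frame(probe_id = character(0), locus_id = character(0),
             reference_taxon = character(0), start = integer(0),
             sequence = character(0), replicates = integer(0),
             stringsAsFactors = FALSE)
}

#' Deduplicate probes by exact sequence
#'
#' Per-species tiling can emit identical probes from different reference
#' rows; the first occurrence (by locus, taxon, start) is kept.
#'
#' @param probes probe data.frame.
#' @return deduplicated probe data.frame.
#' @export
dedupe_probes <- function(probes) {
  probes <- probes[order(probes$locus_id, probes$reference_taxon, probes$start), ,
                   drop = FALSE]
  probes[!duplicated(probes$sequence), , drop = FALSE]
}

#' Replicate probes of short loci up to kit capacity
#'
#' Distinct probes are ordered shortest-locus-first (then by locus id and
#' start) and cycled round-robin, each visit incrementing one probe's
#' replicate count, until the total number of probe copies equals
#' `capacity`.
#'
#' @param probes probe data.frame (distinct probes, `replicates = 1`).
#' @param capacity total probe copies the kit supports (default 57700).
#' @param locus_lengths optional named vector of locus lengths used for the
#'   shortest-first order; inferred from probe coordinates when absent.
#' @return the probes with updated `replicates`, ordered by
#'   (`locus_id`, `start`); `sum(replicates) == capacity`.
#' @export
replicate_to_capacity <- function(probes, capacity = 57700,
                                  locus_lengths = NULL) {
  n <- nrow(probes)
  if (n == 0) stop("no probes to replicate")
  if (n > capacity)
    stop("distinct probe count (", n, ") exceeds kit capacity (", capacity,
         "); reduce the locus set")
  if (is.null(locus_lengths)) {
    probe_len <- nchar(probes$sequence[1])
    locus_lengths <- tapply(probes$start + probe_len, probes$locus_id, max)
  }
  probes$replicates <- 1L
  ord <- order(locus_lengths[probes$locus_id], probes$locus_id, probes$start)
  extra <- capacity - n
  if (extra > 0) {
    bump <- tabulate((seq_len(extra) - 1L) %% n + 1L, nbins = n)
    probes$replicates[ord] <- probes$replicates[ord] + bump
  }
  probes[order(probes$locus_id, probes$start), , drop = FALSE]
}
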