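# Transcriptome scanning: best local-alignment match of a target region
# reference against each transcript, with lineage/representation filters.

# Default pairwise aligner: Smith-Waterman (Biostrings) on both strands.
# Returns list(match_fraction, aligned_length) for the better strand.
local_align_identity <- function(target_seq, transcript_seq) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  score_one <- function(subject) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(target_seq), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    len <- Biostrings::nchar(aln)
    list(match_fraction = if (len > 0) Biostrings::nmatch(aln) / len else 0,
         aligned_length = len)
  }
  fwd <- score_one(transcript_seq)
  rev <- score_one(revcomp(transcript_seq))
  if (fwd$match_fraction >= rev$match_fraction) fwd else rev
}

#' Best transcriptome match for a target region
#'
#' Aligns the target's reference sequence against every transcript on both
#' strands (best local alignment; identity measured over the aligned span)
#' and returns the best hit, or `NULL` when the best identity is strictly
#' below `min_match`.
#'
#' @param target_seqs named character vector of per-species ungapped target
#'   sequences (see [target_sequences()]); the first entry is the reference.
#' @param transcriptome a `seq_records` data.frame of transcripts.
#' @param min_match minimum identity over the aligned span (default 0.55).
#' @param locus_id locus label carried into the hit.
#' @param taxon taxon label of the transcriptome.
#' @param aligner function `(target_seq, transcript_seq)` returning
#'   `list(match_fraction, aligned_length)`; defaults to a both-strand
#'   Smith-Waterman.
#' @return a one-row data.frame (`locus_id`, `taxon`, `transcript_id`,
#'   `match_fraction`, `aligned_length`) or `NULL`.
#' @export
best_transcript_match <- function(target_seqs, transcriptome, min_match = 0.55,
                                  locus_id = NA_character_,
                                  taxon = NA_character_,
                                  aligner = local_align_identity) {
  if (length(target_seqs) == 0) stop("target has no reference sequence")
  ref <- target_seqs[[1]]
  if (is.null(transcriptome) || nrow(transcriptome) == 0) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(transcriptome))) {
    res <- aligner(ref, transcriptome$sequence[i])
    if (is.null(best) || res$match_fraction > best$match_fraction) {
      best <- res
      best$transcript_id <- transcriptome$id[i]
    }
  }
  if (best$match_fraction < min_match) return(NULL)
  data.frame(locus_id = locus_id, taxon = taxon,
             transcript_id = best$transcript_id,
             match_fraction = best$match_fraction,
             aligned_length = best$aligned_length,
             stringsAsFactors = FALSE)
}

#' Assemble an unaligned per-locus sequence set for external alignment
#'
#' Writes the hit sequences of one locus to FASTA and records the external
#' aligner invocation (tool + flags) in a manifest entry; the alignment
#' itself is an external-tool contract whose output is read back with
#' [read_aligned_fasta()].
#'
#' @param hits data.frame of hits for one locus ([best_transcript_match()]
#'   rows) with a `taxon` column.
#' @param sequences named character vector, `transcript_id` -> sequence.
#' @param out_dir directory for the per-locus FASTA.
#' @param locus_id locus label (also the FASTA file stem).
#' @param tool,flags external aligner contract recorded in the manifest.
#' @return `NULL` when fewer than 2 hits (skipped, with a message);
#'   otherwise `list(fasta, n_seqs, invocation)`.
#' @export
assemble_locus_set <- function(hits, sequences, out_dir, locus_id,
                               tool = "mafft",
                               flags = c("--genafpair", "--maxiterate", "1000")) {
  if (is.null(hits) || nrow(hits) < 2) {
    message("locus ", locus_id, ": fewer than 2 hits; skipped")
    return(NULL)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(locus_id, ".fasta"))
  rec <- seq_records(hits$transcript_id, unname(sequences[hits$transcript_id]),
                     taxon = hits$taxon)
  write_fasta(rec, path)
  list(fasta = path, n_seqs = nrow(hits),
       invocation = list(tool = tool, flags = flags,
                         input = path,
                         output = sub("\\.fasta$", ".aln.fasta", path)))
}

#' Lineage and representation filter for a locus alignment
#'
#' Drops the locus when any required anchor taxon is absent, or when more
#' than `max_short` of the remaining rows have ungapped length shorter than
#' `len_fraction` times the maximum ungapped length among the required
#' taxa's rows.
#'
#' @param locus an `aligned_locus`.
#' @param required_taxa character vector of anchor taxa that must be present.
#' @param len_fraction length fraction relative to the anchors (default 0.8).
#' @param max_short maximum tolerated count of short rows (default 2).
#' @return `list(keep = logical, reason = character)`.
#' @export
representation_filter <- function(locus, required_taxa, len_fraction = 0.8,
                                  max_short = 2) {
  missing <- setdiff(required_taxa, locus$taxa)
  if (length(missing) > 0)
    return(list(keep = FALSE,
                reason = paste0("missing required taxon: ",
                                paste(missing, collapse = ", "))))
  lens <- ungapped_length(locus_strings(locus))
  req <- locus$taxa %in% required_taxa
  L <- max(lens[req])
  short <- sum(lens[!req] < len_fraction * L)
  if (short > max_short)
    return(list(keep = FALSE,
                reason = sprintf("%d rows shorter than %.0f%% of anchor length",
                                 short, 100 * len_fraction)))
  list(keep = TRUE, reason = "ok")
}
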