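# End-to-end orchestration of the design and processing pipelines, with a
# serialized configuration, per-stage funnel counts and JSON run manifests.

#' Pipeline configuration
#'
#' Collects every threshold of the toolkit with its default. Defaults
#' mirror the published workflow: candidate loci need >= 6 taxa and a
#' 120-bp window above 50 % identity; targets are >= 150 bp, boundary- and
#' gap-free; homologs need a 55 % match; at most 2 under-length (80 %)
#' rows; 15-mer repeat tallies above 100,000 mask columns; 120-bp probes at
#' 4.0x density fill a 57,700-probe kit; consensus sequences need 35 reads;
#' 20-mer distances drive clustering with 75 % occupancy; trimming uses
#' >70 % column similarity, <10 good sites per 20-bp window, and 10
#' unmasked bases per retained column.
#'
#' @param ... overrides of any default listed above (see the argument list
#'   in the function definition).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_taxa = 6, window = 120, min_identity = 0.5,
                            min_target_len = 150, kmer_exon = 40,
                            min_match = 0.55, len_fraction = 0.8,
                            max_short = 2, kmer_repeat = 15,
                            repeat_threshold = 100000, probe_len = 120,
                            density = 4.0, capacity = 57700, min_reads = 35,
                            kmer_ortho = 20, min_occupancy = 0.75,
                            min_similarity = 0.70, trim_window = 20,
                            min_good = 10, min_unmasked = 10,
                            required_taxa = NULL, sample_map = NULL,
                            seed = 1, ...) {
  cfg <- c(as.list(environment()), list(...))
  cfg$... <- NULL
  stopifnot(cfg$min_identity >= 0, cfg$min_identity <= 1,
            cfg$density > 0, cfg$capacity >= 1, cfg$min_occupancy >= 0,
            cfg$min_occupancy <= 1, cfg$min_similarity >= 0,
            cfg$min_similarity <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the probe-design pipeline
#'
#' Stages: candidate-locus selection, exon-boundary mapping (when genomes
#' are supplied), target-region extraction, optional transcriptome homolog
#' scan with the representation filter, repeat-mask tallying against the
#' genomes, probe tiling and replication to kit capacity. Per-stage counts
#' form a monotone funnel recorded in the run manifest.
#'
#' @param loci list of `aligned_locus` ortholog alignments (rows are
#'   transcript sequences; row taxa identify species).
#' @param config a [pipeline_config()].
#' @param genomes optional `seq_records` of genomes (taxon column matches
#'   locus row taxa) used for exon mapping and repeat tallying.
#' @param transcriptomes optional named list (by taxon) of `seq_records`
#'   used for the homolog scan.
#' @param out_dir optional output directory (probe FASTA, probe key TSV,
#'   mask TSV, manifest JSON).
#' @return list with `probes`, `targets` (data.frame), `target_loci`
#'   (masked `aligned_locus` list), `funnel`, `manifest`.
#' @export
run_design <- function(loci, config = pipeline_config(), genomes = NULL,
                       transcriptomes = NULL, out_dir = NULL) {
  funnel <- list(n_input_loci = length(loci))

  candidates <- filter_ortholog_alignments(
    loci, min_taxa = config$min_taxa, window = config$window,
    min_identity = config$min_identity)
  funnel$n_candidate_loci <- length(candidates)

  # exon boundaries per candidate locus, unioned over species with a genome;
  # genome k-mer vectors are computed once per species
  caches <- list()
  if (!is.null(genomes)) {
    for (gi in seq_len(nrow(genomes)))
      caches[[genomes$taxon[gi]]] <-
        genome_kmer_cache(genomes$sequence[gi], k = config$kmer_exon)
  }
  boundary_sets <- lapply(candidates, function(lc) {
    bounds <- integer(0)
    for (r in seq_len(n_rows(lc))) {
      tx <- lc$taxa[r]
      if (is.null(caches[[tx]])) next
      g <- genomes[genomes$taxon == tx, , drop = FALSE]
      row_str <- locus_strings(lc)[r]
      useq <- gsub("-", "", row_str)
      if (nchar(useq) < config$kmer_exon) next
      em <- suppressWarnings(
        map_exons_by_kmer(useq, g$sequence[1], k = config$kmer_exon,
                          genome_kmers = caches[[tx]]))
      if (length(em$boundaries))
        bounds <- c(bounds, lift_to_alignment(row_str, em$boundaries))
    }
    sort(unique(bounds))
  })

  targets <- list(); target_loci <- list()
  for (i in seq_along(candidates)) {
    lc <- candidates[[i]]
    regs <- select_preliminary_targets(lc, boundaries = boundary_sets[[i]],
                                       min_len = config$min_target_len)
    if (nrow(regs) == 0) next
    targets[[length(targets) + 1L]] <- regs
    for (j in seq_len(nrow(regs))) {
      tl <- locus_slice(lc, regs$start[j], regs$end[j],
                        locus_id = sprintf("%s_t%d", lc$locus_id, j))
      tl$meta$anchor_center <- (n_cols(tl) - 1) / 2
      tl$meta$parent_locus <- lc$locus_id
      target_loci[[length(target_loci) + 1L]] <- tl
    }
  }
  targets <- if (length(targets)) do.call(rbind, targets) else target_region_frame()
  funnel$n_preliminary_targets <- nrow(targets)

  # homolog scan + representation filter (optional)
  scan_report <- NULL
  if (!is.null(transcriptomes)) {
    kept <- logical(length(target_loci))
    rows <- list()
    for (ti in seq_along(target_loci)) {
      tl <- target_loci[[ti]]
      tseqs <- target_sequences(tl, 0, n_cols(tl))
      hits <- list()
      for (tx in names(transcriptomes)) {
        h <- best_transcript_match(tseqs, transcriptomes[[tx]],
                                   min_match = config$min_match,
                                   locus_id = tl$locus_id, taxon = tx)
        if (!is.null(h)) hits[[length(hits) + 1L]] <- h
      }
      hits <- if (length(hits)) do.call(rbind, hits) else NULL
      decision <- list(keep = FALSE, reason = "fewer than 2 homolog hits")
      if (!is.null(hits) && nrow(hits) >= 2) {
        seqs <- vapply(seq_len(nrow(hits)), function(i) {
          tr <- transcriptomes[[hits$taxon[i]]]
          tr$sequence[tr$id == hits$transcript_id[i]]
        }, character(1))
        wmax <- max(nchar(seqs))
        padded <- vapply(seqs, function(s)
          paste0(s, strrep("-", wmax - nchar(s))), character(1))
        msa <- aligned_locus(tl$locus_id, setNames(padded, hits$transcript_id),
                             taxa = hits$taxon)
        decision <- if (is.null(config$required_taxa)) list(keep = TRUE, reason = "ok")
          else representation_filter(msa, config$required_taxa,
                                     len_fraction = config$len_fraction,
                                     max_short = config$max_short)
      }
      kept[ti] <- decision$keep
      rows[[ti]] <- data.frame(locus_id = tl$locus_id,
                               n_hits = if (is.null(hits)) 0L else nrow(hits),
                               keep = decision$keep, reason = decision$reason,
                               stringsAsFactors = FALSE)
    }
    scan_report <- do.call(rbind, rows)
    target_loci <- target_loci[kept]
  }
  funnel$n_scanned_loci <- length(target_loci)

  # repeat masking
  mask_report <- NULL
  if (!is.null(genomes) && length(target_loci) > 0) {
    db <- build_kmer_db(target_loci, k = config$kmer_repeat, neighbors = 1)
    tallies <- lapply(seq_len(nrow(genomes)), function(gi) {
      tally_genome(db, genomes$sequence[gi], genome_id = genomes$id[gi])
    })
    target_loci <- lapply(target_loci, mask_high_copy, tallies = tallies,
                          threshold = config$repeat_threshold)
    mask_report <- do.call(rbind, lapply(target_loci, function(tl) {
      mcols <- which(apply(tl$mask, 2, any)) - 1L
      if (length(mcols) == 0) return(NULL)
      data.frame(locus_id = tl$locus_id, column = mcols,
                 stringsAsFactors = FALSE)
    }))
  }
  funnel$n_masked_columns <- if (is.null(mask_report)) 0L else nrow(mask_report)

  # probe tiling per reference row, deduplicated by sequence
  probes <- list()
  for (tl in target_loci) {
    col_mask <- apply(tl$mask, 2, any)
    for (r in seq_len(n_rows(tl))) {
      row_seq <- paste(tl$seqs[r, ], collapse = "")   # targets are gap-free
      p <- tile_probes(row_seq, mask = col_mask, probe_len = config$probe_len,
                       density = config$density, locus_id = tl$locus_id,
                       reference_taxon = tl$taxa[r])
      if (nrow(p)) probes[[length(probes) + 1L]] <- p
    }
  }
  probes <- if (length(probes)) dedupe_probes(do.call(rbind, probes))
            else probe_frame()
  funnel$n_distinct_probes <- nrow(probes)
  if (nrow(probes) > 0)
    probes <- replicate_to_capacity(probes, capacity = config$capacity)
  funnel$n_probe_copies <- sum(probes$replicates)

  manifest <- list(pipeline = "design", config = unclass(config),
                   funnel = funnel,
                   scan = if (!is.null(scan_report))
                     list(n_kept = sum(scan_report$keep)) else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(probes) > 0) {
      write_fasta(seq_records(probes$probe_id, probes$sequence,
                              taxon = probes$reference_taxon),
                  file.path(out_dir, "probes.fasta"))
      write.table(probes[, c("probe_id", "locus_id", "reference_taxon",
                             "start", "replicates")],
                  file.path(out_dir, "probe_key.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(mask_report))
      write.table(mask_report, file.path(out_dir, "mask.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    write_manifest(manifest, file.path(out_dir, "design_manifest.json"))
  }
  list(probes = probes, targets = targets, target_loci = target_loci,
       scan_report = scan_report, funnel = funnel, manifest = manifest)
}

#' Run the post-capture processing pipeline
#'
#' Stages: read-support filtering, per-locus orthology clustering with the
#' species constraint, taxon-occupancy filtering, alignment (simulated
#' consensus sets are indel-free and stack directly; unequal-length sets
#' are right-padded and flagged for external realignment in the manifest),
#' trimming/masking, supermatrix concatenation and dataset statistics.
#'
#' @param consensus a `seq_records` data.frame with an added `locus` column
#'   assigning each record to its target locus.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (trimmed FASTA per locus,
#'   relaxed PHYLIP + partitions, stats TSVs, runner manifests).
#' @return list with `clusters` (per locus), `trimmed` (list of
#'   `aligned_locus`), `supermatrix`, `stats`, `locus_stats`, `regression`,
#'   `funnel`, `manifest`.
#' @export
run_process <- function(consensus, config = pipeline_config(),
                        out_dir = NULL) {
  stopifnot("locus" %in% names(consensus))
  if (!is.null(config$sample_map))
    consensus <- apply_sample_map(consensus, config$sample_map)
  funnel <- list(n_consensus = nrow(consensus))
  if (nrow(consensus) == 0) {
    warning("empty consensus input; nothing to process")
    return(list(clusters = list(), trimmed = list(), supermatrix = NULL,
                stats = NULL, locus_stats = NULL, regression = NULL,
                funnel = funnel, manifest = list(pipeline = "process",
                                                 funnel = funnel)))
  }
  n_species_total <- length(unique(consensus$taxon))

  filtered <- filter_consensus(consensus, min_reads = config$min_reads)
  funnel$n_supported <- nrow(filtered)

  cluster_rows <- list(); kept_loci <- list()
  for (loc in sort(unique(filtered$locus))) {
    recs <- filtered[filtered$locus == loc, , drop = FALSE]
    cl <- cluster_orthologs(recs, k = config$kmer_ortho)
    kept <- filter_clusters(cl, n_species_total,
                            min_fraction = config$min_occupancy)
    for (ci in seq_along(cl)) {
      cluster_rows[[length(cluster_rows) + 1L]] <-
        data.frame(locus = loc, cluster = cl[[ci]]$cluster_id,
                   n_species = length(cl[[ci]]$species_set),
                   kept = any(vapply(kept, function(kc)
                     identical(kc$cluster_id, cl[[ci]]$cluster_id),
                     logical(1))),
                   stringsAsFactors = FALSE)
    }
    for (ci in seq_along(kept)) {
      m <- kept[[ci]]$members
      wmax <- max(nchar(m$sequence))
      padded <- paste0(m$sequence, strrep("-", wmax - nchar(m$sequence)))
      locus_id <- if (length(kept) > 1) sprintf("L%03d_c%d", loc, ci)
                  else sprintf("L%03d", loc)
      kept_loci[[length(kept_loci) + 1L]] <-
        aligned_locus(locus_id, setNames(padded, m$id), taxa = m$taxon)
    }
  }
  funnel$n_clusters_kept <- length(kept_loci)

  trimmed <- lapply(kept_loci, function(lc) {
    trim_alignment(lc, min_similarity = config$min_similarity,
                   window = config$trim_window, min_good = config$min_good,
                   min_unmasked = config$min_unmasked)
  })
  trimmed <- Filter(function(lc) n_cols(lc) > 0, trimmed)
  funnel$n_loci_final <- length(trimmed)

  sm <- NULL; stats <- NULL; locus_stats <- NULL; regression <- NULL
  if (length(trimmed) > 0) {
    # supermatrix rows are species; trimmed loci carry record ids as row ids
    sm_loci <- lapply(trimmed, function(lc) {
      lc$ids <- lc$taxa
      rownames(lc$seqs) <- lc$taxa
      lc
    })
    sm <- concatenate(sm_loci, taxon_universe = sort(unique(consensus$taxon)))
    stats <- matrix_stats(sm)
    locus_stats <- per_locus_stats(trimmed)
    if (nrow(locus_stats) >= 3 && stats::var(locus_stats$length) > 0)
      regression <- pic_length_regression(locus_stats)
  }

  manifest <- list(pipeline = "process", config = unclass(config),
                   funnel = funnel,
                   runners = list(
                     raxml = list(tool = "raxml", model = "GTRGAMMA",
                                  ras_replicates = 1000, bootstraps = 1000,
                                  partitions = "per locus"),
                     astral = list(tool = "astral",
                                   input = "per-locus ML gene trees")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (lc in trimmed)
      write_aligned_fasta(lc, file.path(out_dir, paste0(lc$locus_id, ".trimmed.fasta")))
    if (!is.null(sm)) {
      write_phylip_and_partitions(sm, file.path(out_dir, "supermatrix"))
      write.table(stats, file.path(out_dir, "dataset_stats.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(locus_stats, file.path(out_dir, "locus_stats.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(manifest, file.path(out_dir, "process_manifest.json"))
  }
  list(clusters = if (length(cluster_rows)) do.call(rbind, cluster_rows) else NULL,
       trimmed = trimmed, supermatrix = sm, stats = stats,
       locus_stats = locus_stats, regression = regression,
       funnel = funnel, manifest = manifest)
}
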