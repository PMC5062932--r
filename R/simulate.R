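# Seeded simulation of a clade with exon/intron gene structure, planted
# high-copy repeats and gene duplications, plus read and consensus-set
# generators. All stages draw from named substreams of one run seed, so a
# fixed seed gives byte-identical output and each stage is independently
# reproducible.

#' Specification of a simulated clade
#'
#' Defaults describe a desk-scale mygalomorph-like study system: a dozen
#' species separated by up to ~0.4 substitutions/site on the deepest path
#' (JC expected pairwise identity around two thirds), loci of one to three
#' exons of 150-400 bp separated by longer introns evolving faster than
#' exons, one microsatellite-like high-copy element embedded in the first
#' locus, and consensus read support drawn from a negative binomial with
#' most mass well above the read-support filter.
#'
#' @param seed integer run seed (all randomness derives from it).
#' @param n_species number of species (ignored when `tree` is given).
#' @param tree optional fixed newick string; otherwise a random
#'   birth-death tree is drawn.
#' @param tree_height root-to-tip height in expected substitutions/site.
#' @param n_loci number of target loci.
#' @param n_exons_range,exon_length_range,intron_length_range sampling
#'   ranges (inclusive) for gene structure.
#' @param intron_rate_multiplier relative substitution rate of introns.
#' @param anchor_span,anchor_rate width (bases, centered on the spliced
#'   transcript) and relative substitution rate of the conserved anchor
#'   core of each locus. Capture loci are anchored on cores under strong
#'   purifying selection with faster-evolving flanks; the rate profile is
#'   what makes a locus an "anchor plus flank" target.
#' @param duplications list of events, each
#'   `list(taxa = <tip labels>, loci = <locus indices>, divergence = <t>)`;
#'   the duplicate copy arises on the branch to the MRCA of `taxa` with the
#'   given extra divergence.
#' @param repeats list of planted elements, each `list(motif, copies,
#'   in_locus = <locus index or NA>, span = <bases embedded in the locus>)`.
#'   The default plants a microsatellite at a genomic copy number high
#'   enough to behave as a true high-copy element (the class the masking
#'   threshold exists for in repeat-rich Gb-scale genomes); pass
#'   `repeats = list()` for repeat-free clades.
#' @param read_length,coverage,read_error read-simulation model.
#' @param consensus_error per-base error of consensus sequences.
#' @param read_support_mu,read_support_size negative-binomial parameters of
#'   the supporting-read-count distribution.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(seed = 1, n_species = 12, tree = NULL, tree_height = 0.2,
                     n_loci = 20, n_exons_range = c(1, 3),
                     exon_length_range = c(150, 400),
                     intron_length_range = c(80, 300),
                     intron_rate_multiplier = 3,
                     anchor_span = 160, anchor_rate = 0.25,
                     duplications = list(),
                     repeats = list(list(motif = "CAG", copies = 150000,
                                         in_locus = 1, span = 45)),
                     read_length = 150, coverage = 20, read_error = 0.005,
                     consensus_error = 0.002,
                     read_support_mu = 150, read_support_size = 3) {
  spec <- as.list(environment())
  stopifnot(spec$tree_height >= 0, spec$coverage >= 0, spec$read_error >= 0)
  for (rp in spec$repeats) stopifnot(rp$copies >= 0)
  class(spec) <- "sim_spec"
  spec
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# sample from an inclusive integer range, robust to degenerate ranges
sample_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# JC substitution over branch length t (expected substitutions/site, scalar
# or per-site vector): each site changes with prob 3/4 (1 - exp(-4/3 t)),
# uniformly to another base.
evolve_seq <- function(chars, t) {
  if (all(t <= 0)) return(chars)
  p <- 0.75 * (1 - exp(-4 / 3 * t))
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  chars
}

# Recursive propagation of one locus down the tree. `state` is a list of
# copies; each copy is list(exons = list of char vectors,
# introns = list of char vectors). Duplication events keyed by node number.
propagate_locus <- function(tree, node, state, branch_len, dup_at_node,
                            intron_mult, exon_rates) {
  evolve_copy <- function(copy, t) {
    copy$exons <- lapply(seq_along(copy$exons), function(e)
      evolve_seq(copy$exons[[e]], t * exon_rates[[e]]))
    copy$introns <- lapply(copy$introns, evolve_seq, t = t * intron_mult)
    copy
  }
  state <- lapply(state, evolve_copy, t = branch_len)
  if (!is.null(dup_at_node[[as.character(node)]])) {
    div <- dup_at_node[[as.character(node)]]
    state[[length(state) + 1L]] <- evolve_copy(state[[length(state)]], div)
  }
  ntips <- length(tree$tip.label)
  if (node <= ntips) {
    out <- list()
    out[[tree$tip.label[node]]] <- state
    return(out)
  }
  children <- tree$edge[tree$edge[, 1] == node, 2]
  out <- list()
  for (ch in children) {
    bl <- tree$edge.length[tree$edge[, 1] == node & tree$edge[, 2] == ch]
    out <- c(out, propagate_locus(tree, ch, state, bl, dup_at_node,
                                  intron_mult, exon_rates))
  }
  out
}

#' Simulate a clade: genomes, transcriptomes and truth tables
#'
#' Generates a species tree, evolves each locus (exons plus introns) down
#' it under a Jukes-Cantor substitution process, plants duplications and
#' high-copy repeat elements, and assembles per-species genomes (loci in
#' genomic form, plus a repeat field) and transcriptomes (spliced exons,
#' one transcript per gene copy).
#'
#' @param spec a [sim_spec()].
#' @return list with `tree` (ape phylo), `species`, `genomes`
#'   (`seq_records`, one per species), `transcriptomes` (named list of
#'   `seq_records` per species) and `truth` (list of data.frames:
#'   `exon_boundaries`, `layout`, `orthologs`, `repeats`).
#' @export
simulate_clade <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(derive_seed(spec$seed, "tree"))
  tree <- if (!is.null(spec$tree)) ape::read.tree(text = spec$tree)
          else ape::rphylo(spec$n_species, birth = 1, death = 0)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth > 0) tree$edge.length <- tree$edge.length / depth * spec$tree_height
  if (is.null(spec$tree)) tree$tip.label <- sprintf("sp%02d", seq_along(tree$tip.label))
  species <- tree$tip.label
  ntips <- length(species)
  root <- ntips + 1L

  # duplication events -> per-locus map: node number -> divergence
  dup_maps <- vector("list", spec$n_loci)
  for (ev in spec$duplications) {
    if (!all(ev$taxa %in% species))
      stop("duplication names absent tips: ",
           paste(setdiff(ev$taxa, species), collapse = ", "))
    node <- if (length(ev$taxa) == 1) match(ev$taxa, species)
            else ape::getMRCA(tree, ev$taxa)
    for (li in ev$loci) {
      dup_maps[[li]] <- c(dup_maps[[li]] %||% list(),
                          setNames(list(ev$divergence), as.character(node)))
    }
  }

  set.seed(derive_seed(spec$seed, "loci"))
  locus_structs <- lapply(seq_len(spec$n_loci), function(li) {
    n_ex <- sample_range(spec$n_exons_range, 1)
    ex_len <- sample_range(spec$exon_length_range, n_ex)
    in_len <- if (n_ex > 1) sample_range(spec$intron_length_range, n_ex - 1)
              else integer(0)
    exons <- lapply(ex_len, function(n) strsplit(random_dna(n), "")[[1]])
    introns <- lapply(in_len, function(n) strsplit(random_dna(n), "")[[1]])
    # conserved anchor core: `anchor_span` transcript bases centered on the
    # spliced transcript evolve at `anchor_rate` x the base rate
    tot <- sum(ex_len)
    a_lo <- max(0L, floor((tot - spec$anchor_span) / 2))
    a_hi <- min(tot, a_lo + spec$anchor_span)
    offs <- c(0L, cumsum(ex_len))
    rates <- lapply(seq_along(ex_len), function(e) {
      pos <- seq(offs[e], offs[e + 1L] - 1L)   # 0-based transcript coords
      ifelse(pos >= a_lo & pos < a_hi, spec$anchor_rate, 1)
    })
    list(exons = exons, introns = introns, rates = rates)
  })
  # embed planted repeats into exon 1 of their target locus (ancestral state)
  for (rp in spec$repeats) {
    li <- rp$in_locus %||% NA
    if (!is.na(li) && !is.null(rp$span) && rp$span > 0) {
      motif_chars <- strsplit(rp$motif, "")[[1]]
      fill <- rep(motif_chars, length.out = rp$span)
      ex <- locus_structs[[li]]$exons[[1]]
      at <- max(1L, floor((length(ex) - rp$span) / 2))
      ex[seq(at, at + rp$span - 1L)] <- fill
      locus_structs[[li]]$exons[[1]] <- ex
    }
  }

  set.seed(derive_seed(spec$seed, "evolve"))
  per_locus_tips <- lapply(seq_len(spec$n_loci), function(li) {
    state <- list(list(exons = locus_structs[[li]]$exons,
                       introns = locus_structs[[li]]$introns))
    propagate_locus(tree, root, state, 0, dup_maps[[li]] %||% list(),
                    spec$intron_rate_multiplier, locus_structs[[li]]$rates)
  })

  set.seed(derive_seed(spec$seed, "repeats"))
  genomes <- list(); transcriptomes <- list()
  layout <- list(); boundaries <- list(); repeats_truth <- list()
  for (sp in species) {
    gparts <- character(0); pos <- 0L
    trecs <- list()
    for (li in seq_len(spec$n_loci)) {
      copies <- per_locus_tips[[li]][[sp]]
      for (ci in seq_along(copies)) {
        copy <- copies[[ci]]
        pieces <- character(0)
        ex_str <- vapply(copy$exons, paste, character(1), collapse = "")
        in_str <- vapply(copy$introns, paste, character(1), collapse = "")
        for (e in seq_along(ex_str)) {
          pieces <- c(pieces, ex_str[e])
          if (e < length(ex_str)) pieces <- c(pieces, in_str[e])
        }
        gseq <- paste(pieces, collapse = "")
        layout[[length(layout) + 1L]] <-
          data.frame(species = sp, locus = li, copy = ci, start = pos,
                     end = pos + nchar(gseq), stringsAsFactors = FALSE)
        gparts <- c(gparts, gseq)
        pos <- pos + nchar(gseq)
        transcript <- paste(ex_str, collapse = "")
        tid <- sprintf("%s_L%03d_c%d", sp, li, ci)
        trecs[[tid]] <- transcript
        cuts <- head(cumsum(nchar(ex_str)), -1)
        boundaries[[length(boundaries) + 1L]] <-
          data.frame(species = sp, locus = li, copy = ci,
                     transcript_id = tid,
                     boundaries = paste(cuts, collapse = ","),
                     transcript_length = nchar(transcript),
                     stringsAsFactors = FALSE)
      }
    }
    for (rp in spec$repeats) {
      if (rp$copies > 0) {
        block <- paste(rep(rp$motif, rp$copies), collapse = "")
        repeats_truth[[length(repeats_truth) + 1L]] <-
          data.frame(species = sp, motif = rp$motif, start = pos,
                     end = pos + nchar(block), stringsAsFactors = FALSE)
        gparts <- c(gparts, block)
        pos <- pos + nchar(block)
      }
    }
    genomes[[sp]] <- paste(gparts, collapse = "")
    transcriptomes[[sp]] <- seq_records(names(trecs), unlist(trecs),
                                        taxon = sp, sample = sp)
  }
  genome_recs <- seq_records(paste0(species, "_genome"), unlist(genomes),
                             taxon = species, sample = species)
  list(tree = tree, species = species, spec = spec,
       genomes = genome_recs, transcriptomes = transcriptomes,
       truth = list(
         exon_boundaries = do.call(rbind, boundaries),
         layout = do.call(rbind, layout),
         repeats = if (length(repeats_truth)) do.call(rbind, repeats_truth)
                   else NULL))
}

#' Simulate shotgun reads from a sequence
#'
#' Uniform-start reads from both strands with independent per-base
#' substitution errors. The read count is
#' `round(coverage * L / length)`; ids record the 0-based origin and
#' strand.
#'
#' @param genome single-row `seq_records` or string.
#' @param length read length (default 150).
#' @param coverage mean per-base coverage (default 20).
#' @param error per-base substitution error rate (default 0.005).
#' @param seed integer seed.
#' @return `seq_records` with ids `read<i>|<start>|<+/->`.
#' @export
simulate_reads <- function(genome, length = 150, coverage = 20,
                           error = 0.005, seed = 1) {
  gseq <- if (is.data.frame(genome)) genome$sequence[1] else normalize_sequence(genome)
  L <- nchar(gseq)
  stopifnot(coverage > 0, length <= L)
  set.seed(as.integer(seed %% 2147483647))
  n_reads <- round(coverage * L / length)
  starts <- sample.int(L - length + 1L, n_reads, replace = TRUE) - 1L
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(gseq, starts + 1L, starts + length)
  if (error > 0) {
    seqs <- vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      paste(evolve_err(chars, error), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  rev <- strands == "-"
  seqs[rev] <- revcomp(seqs[rev])
  ids <- sprintf("read%06d|%d|%s", seq_len(n_reads), starts, strands)
  seq_records(ids, seqs, taxon = "reads", sample = "reads")
}

# uniform substitution error at rate `e` per base
evolve_err <- function(chars, e) {
  hit <- runif(length(chars)) < e
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  chars
}

#' Simulate per-sample consensus sequences with read support
#'
#' Emits one consensus record per (species, locus, gene copy): the spliced
#' transcript with a small per-base error, annotated with a supporting-read
#' count drawn from the [sim_spec()]'s negative-binomial distribution. Paralogous
#' copies appear as separate records, mirroring an assembler that splits
#' gene copies above ~5 % divergence.
#'
#' @param sim result of [simulate_clade()].
#' @param seed integer seed (default: derived from the [sim_spec()] seed).
#' @return `list(records, truth)`: `records` is a `seq_records` with
#'   `read_support`; `truth` maps each record id to (species, locus, copy).
#' @export
simulate_consensus_set <- function(sim, seed = NULL) {
  spec <- sim$spec
  set.seed(seed %||% derive_seed(spec$seed, "consensus"))
  ids <- character(0); seqs <- character(0); taxa <- character(0)
  truth <- list()
  for (sp in sim$species) {
    trecs <- sim$transcriptomes[[sp]]
    for (i in seq_len(nrow(trecs))) {
      chars <- strsplit(trecs$sequence[i], "")[[1]]
      if (spec$consensus_error > 0) chars <- evolve_err(chars, spec$consensus_error)
      ids <- c(ids, sub("_L", "_cons_L", trecs$id[i]))
      seqs <- c(seqs, paste(chars, collapse = ""))
      taxa <- c(taxa, sp)
      meta <- sim$truth$exon_boundaries[
        sim$truth$exon_boundaries$transcript_id == trecs$id[i], ]
      truth[[length(truth) + 1L]] <-
        data.frame(id = ids[length(ids)], species = sp,
                   locus = meta$locus[1], copy = meta$copy[1],
                   stringsAsFactors = FALSE)
    }
  }
  support <- rnbinom(length(ids), mu = spec$read_support_mu,
                     size = spec$read_support_size)
  records <- seq_records(ids, seqs, taxon = taxa, sample = taxa,
                         read_support = support)
  list(records = records, truth = do.call(rbind, truth))
}
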