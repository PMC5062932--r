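Package: anchorforge
Title: Probe Design and Post-Capture Processing for Anchored Hybrid Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for anchored hybrid enrichment (AHE) phylogenomics in
    non-model clades. The design half selects conserved target regions from
    ortholog alignments (taxon-count and sliding-window identity filters),
    maps exon boundaries from genomes (40-mer chaining) or raw reads
    (mismatch discordance), scans transcriptomes for homologs, masks
    high-copy regions by 15-mer genome tallies, and tiles 120-bp capture
    probes at fixed density with replication to kit capacity. The processing
    half filters assembled consensus sequences by read support, clusters
    homologs into species-constrained ortholog sets by 20-mer distances,
    trims and masks alignments with sliding-window quality rules, and builds
    partitioned supermatrices with parsimony-informativeness statistics.
    A seeded simulator of clades with exon/intron structure, planted repeats
    and gene duplications provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    ape,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
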