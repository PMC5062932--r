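small_spec <- function(seed = 1, ...) {
  sim_spec(seed = seed, n_species = 4, n_loci = 3,
           exon_length_range = c(150, 200), intron_length_range = c(60, 100),
           repeats = list(), ...)
}

test_that("a fixed seed reproduces the clade byte for byte", {
  a <- simulate_clade(small_spec(seed = 9))
  b <- simulate_clade(small_spec(seed = 9))
  expect_identical(a$genomes$sequence, b$genomes$sequence)
  expect_identical(a$transcriptomes, b$transcriptomes)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_clade(small_spec(seed = 10))
  expect_false(identical(a$genomes$sequence, c_$genomes$sequence))
})

test_that("zero substitution rate yields identical sequences across species", {
  sim <- simulate_clade(small_spec(seed = 2, tree_height = 0))
  for (li in 1:3) {
    tb <- sim$truth$exon_boundaries
    rows <- tb[tb$locus == li, ]
    seqs <- vapply(seq_len(nrow(rows)), function(i) {
      tr <- sim$transcriptomes[[rows$species[i]]]
      tr$sequence[tr$id == rows$transcript_id[i]]
    }, character(1))
    expect_length(unique(seqs), 1)
  }
  # one species, intronless locus, rate 0: transcript is a genome substring
  s1 <- sim_spec(seed = 3, n_species = 2, n_loci = 1, tree_height = 0,
                 n_exons_range = c(1, 1), repeats = list())
  sim1 <- simulate_clade(s1)
  tr <- sim1$transcriptomes[[1]]$sequence[1]
  expect_true(grepl(tr, sim1$genomes$sequence[1], fixed = TRUE))
})

test_that("pairwise divergence follows the Jukes-Cantor expectation", {
  # two tips at height t: expected differing fraction 3/4 (1 - e^{-4/3 * 2t})
  spec <- sim_spec(seed = 4, tree = "(A:0.1,B:0.1);", tree_height = 0.1,
                   n_loci = 1, n_exons_range = c(1, 1),
                   exon_length_range = c(10000, 10000),
                   anchor_span = 0, repeats = list())
  sim <- simulate_clade(spec)
  a <- strsplit(sim$transcriptomes[["A"]]$sequence[1], "")[[1]]
  b <- strsplit(sim$transcriptomes[["B"]]$sequence[1], "")[[1]]
  p_hat <- mean(a != b)
  p_exp <- 0.75 * (1 - exp(-4 / 3 * 0.2))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("read simulation respects the count arithmetic and maps back exactly", {
  set.seed(91)
  g <- rand_seq(3000)
  reads <- simulate_reads(g, length = 150, coverage = 20, error = 0, seed = 12)
  expect_equal(nrow(reads), round(20 * 3000 / 150))
  # error-free reads match their origin exactly
  meta <- strsplit(reads$id, "|", fixed = TRUE)
  for (i in sample(nrow(reads), 40)) {
    start <- as.integer(meta[[i]][2]); strand <- meta[[i]][3]
    frag <- substr(g, start + 1, start + 150)
    if (strand == "-") frag <- revcomp(frag)
    expect_identical(reads$sequence[i], frag)
  }
  # high coverage: every base away from the edge ramp is covered
  cov <- integer(3000)
  for (m in meta) {
    s <- as.integer(m[2]); cov[(s + 1):(s + 150)] <- cov[(s + 1):(s + 150)] + 1L
  }
  expect_true(all(cov[76:2925] > 0))
})

test_that("consensus sets mirror gene copies and interact with the read filter", {
  spec <- small_spec(seed = 5,
                     duplications = list(list(taxa = c("sp01", "sp02"),
                                              loci = 2, divergence = 0.15)))
  sim <- simulate_clade(spec)
  cs <- simulate_consensus_set(sim)
  # no duplication: one record per (species, locus); duplicated locus gets
  # a second record in the affected subtree
  tab <- table(cs$truth$species, cs$truth$locus)
  expect_true(all(tab[, c(1, 3)] == 1))
  expect_setequal(unique(cs$truth$copy[cs$truth$locus == 2]), c(1, 2))
  expect_identical(cs$records$id, cs$truth$id)

  # degenerate support at 34 reads: the consensus filter removes everything
  low <- cs$records
  low$read_support <- 34L
  expect_equal(nrow(filter_consensus(low)), 0L)
})
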