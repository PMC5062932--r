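test_that("consensus filtering removes records below the read-support minimum", {
  recs <- rand_records(3, support = c(34L, 35L, 36L))
  kept <- filter_consensus(recs)
  expect_equal(kept$read_support, c(35L, 36L))

  expect_equal(nrow(filter_consensus(rand_records(0))), 0L)

  set.seed(61)
  recs <- rand_records(100)
  expect_equal(nrow(filter_consensus(recs)),
               sum(vapply(recs$read_support, function(x) x >= 35, logical(1))))

  recs$read_support[5] <- NA_integer_
  expect_error(filter_consensus(recs), "r005")
})

test_that("k-mer profiles contain contiguous and every-third-position k-mers", {
  # "ACGTAC", k=3: the strided part needs a 7-base span, so only the four
  # contiguous 3-mers appear
  p <- kmer_profile("ACGTAC", k = 3)
  expect_setequal(p$kmers, c("ACG", "CGT", "GTA", "TAC"))

  # 9 bases admit strided 3-mers at positions 0..2 (stride-3 diagonals)
  p9 <- kmer_profile("ACGTACGTA", k = 3)
  expect_true(all(c("ATG", "CAT", "GCA") %in% p9$kmers))

  hp <- kmer_profile(strrep("A", 50), k = 20)
  expect_equal(hp$kmers, strrep("A", 20))

  expect_length(kmer_profile("ACGT", k = 20)$kmers, 0)

  # monotone under suffix extension
  set.seed(62)
  s <- rand_seq(80)
  expect_true(all(kmer_profile(s, 20)$kmers %in%
                  kmer_profile(paste0(s, rand_seq(20)), 20)$kmers))

  # N-containing k-mers are excluded
  pn <- kmer_profile("ACGTNACGT", k = 4)
  expect_false(any(grepl("N", pn$kmers)))
})

test_that("pair distance is the k-mer Jaccard and matches the oracle", {
  set.seed(63)
  s <- rand_seq(100)
  expect_equal(pair_distance(kmer_profile(s), kmer_profile(s)), 0)

  a <- kmer_profile(strrep("A", 40), k = 20)
  c_ <- kmer_profile(strrep("C", 40), k = 20)
  expect_equal(pair_distance(a, c_), 1)

  for (i in 1:25) {
    x <- rand_seq(100)
    y_chars <- strsplit(x, "")[[1]]
    flip <- sample(100, sample(1:6, 1))
    for (f in flip) y_chars[f] <- sample(setdiff(BASES, y_chars[f]), 1)
    y <- paste(y_chars, collapse = "")
    expect_equal(pair_distance(kmer_profile(x, 20), kmer_profile(y, 20)),
                 oracle_distance(x, y, 20))
  }

  expect_error(pair_distance(kmer_profile(s, 20), kmer_profile(s, 15)),
               "different k")
  expect_warning(d <- pair_distance(kmer_profile("ACG", 20),
                                    kmer_profile("TGA", 20)), "empty")
  expect_equal(d, 1)

  # symmetry / bounds / identity on random profiles
  set.seed(64)
  for (i in 1:20) {
    p1 <- kmer_profile(rand_seq(60), 20); p2 <- kmer_profile(rand_seq(60), 20)
    d12 <- pair_distance(p1, p2)
    expect_equal(d12, pair_distance(p2, p1))
    expect_gte(d12, 0); expect_lte(d12, 1)
  }
})

test_that("clustering groups one sequence per species and matches the naive reference", {
  set.seed(65)
  # mutually similar single-copy homologs -> one cluster with every taxon
  base <- rand_seq(300)
  taxa <- sprintf("sp%02d", 1:6)
  seqs <- vapply(taxa, function(t) {
    chars <- strsplit(base, "")[[1]]
    flip <- sample(300, 4)
    for (f in flip) chars[f] <- sample(setdiff(BASES, chars[f]), 1)
    paste(chars, collapse = "")
  }, character(1))
  recs <- seq_records(paste0(taxa, "_c1"), seqs, taxon = taxa)
  cl <- cluster_orthologs(recs)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$species_set, taxa)

  # agreement with the O(n^3) reference on random instances (<= 12 seqs)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    recs <- seq_records(sprintf("h%02d", 1:n),
                        vapply(1:n, function(j) rand_seq(80), character(1)),
                        taxon = sample(sprintf("sp%d", 1:4), n, replace = TRUE))
    d <- distance_matrix(recs)
    got <- lapply(cluster_orthologs(recs, dist = d),
                  function(cl) sort(cl$members$id))
    want <- oracle_cluster(recs, d)
    expect_equal(got, want)
    # hard invariant: never two sequences from one taxon
    for (cl in cluster_orthologs(recs, dist = d))
      expect_false(anyDuplicated(cl$members$taxon) > 0)
  }
})

test_that("a duplication on an internal branch yields a full and a partial cluster", {
  set.seed(66)
  sp <- sim_spec(seed = 17, n_loci = 1, tree_height = 0.012,
                 tree = "((sp01:0.3,sp02:0.3):0.7,((sp03:0.3,sp04:0.3):0.2,sp05:0.5):0.5);",
                 repeats = list(), consensus_error = 0,
                 duplications = list(list(taxa = c("sp01", "sp02"), loci = 1,
                                          divergence = 0.15)))
  sim <- simulate_clade(sp)
  cs <- simulate_consensus_set(sim)
  cl <- cluster_orthologs(cs$records)
  truth <- split(cs$truth$id, cs$truth$copy)
  got <- lapply(cl, function(c) sort(c$members$id))
  expect_setequal(lapply(truth, sort), got)
  sizes <- sort(vapply(cl, function(c) length(c$species_set), integer(1)))
  expect_equal(sizes[length(sizes)], 5L)       # copy-1 cluster spans the clade
  expect_lt(sizes[1], 5L)                      # duplicate copy is a subclade
})

test_that("occupancy filtering keeps clusters at exactly the threshold", {
  mk_cluster <- function(n_sp) {
    taxa <- sprintf("sp%02d", seq_len(n_sp))
    list(cluster_id = 1L,
         members = seq_records(paste0(taxa, "_x"), rep("ACGT", n_sp),
                               taxon = taxa),
         species_set = taxa)
  }
  # species-count arithmetic at a 33-species study: 25/33 = 0.758 kept,
  # 24/33 = 0.727 removed
  expect_length(filter_clusters(list(mk_cluster(25)), 33), 1)
  expect_length(filter_clusters(list(mk_cluster(24)), 33), 0)
  expect_length(filter_clusters(list(mk_cluster(33)), 33), 1)
  expect_length(filter_clusters(list(mk_cluster(3)), 4, min_fraction = 0.75), 1)
  expect_length(filter_clusters(list(mk_cluster(2)), 33, min_fraction = 0), 1)
})
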