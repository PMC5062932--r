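test_that("k-mer database enumerates observed k-mers plus distance-1 neighbors", {
  lc <- aligned_locus("L1", c(r1 = "AAAA"))
  db <- build_kmer_db(list(lc), k = 3, neighbors = 1)
  # AAA at columns 0 and 1, plus 9 substitution neighbors each
  expect_equal(nrow(db), 20L)
  expect_equal(length(unique(db$kmer)), 10L)
  expect_setequal(unique(db$column), c(0L, 1L))
  # neighbors are at Hamming distance exactly <= 1 from AAA
  hd <- vapply(unique(db$kmer), function(km)
    sum(strsplit(km, "")[[1]] != c("A", "A", "A")), integer(1))
  expect_true(all(hd <= 1))

  # size bound: <= m * (1 + 3k) keys for m observed k-mers
  set.seed(51)
  lc2 <- rand_locus(2, 60)
  db15 <- build_kmer_db(list(lc2), k = 15)
  m <- 2 * (60 - 15 + 1)
  expect_lte(length(unique(db15$kmer)), m * 46)

  expect_equal(nrow(build_kmer_db(list(), k = 15)), 0L)
})

test_that("genome tallies equal the brute-force dictionary count", {
  set.seed(52)
  for (i in 1:6) {
    lc <- rand_locus(2, 30, locus_id = sprintf("L%d", i))
    db <- build_kmer_db(list(lc), k = 7, neighbors = 1)
    genome <- rand_seq(800)
    got <- tally_genome(db, genome, genome_id = "g")
    want <- oracle_tally(as.data.frame(db), genome, k = 7)
    got_keys <- paste(got$locus_id, got$column, sep = "\r")
    expect_setequal(got_keys, names(want))
    for (j in seq_len(nrow(got)))
      expect_equal(got$count[j], unname(want[[got_keys[j]]]))
  }

  # zero-hit genome
  lcA <- aligned_locus("LA", c(r = strrep("A", 30)))
  dbA <- build_kmer_db(list(lcA), k = 15, neighbors = 0)
  expect_equal(nrow(tally_genome(dbA, strrep("G", 500))), 0L)
})

test_that("tallies double when the genome is self-concatenated, up to junction effects", {
  set.seed(53)
  lc <- rand_locus(2, 40)
  db <- build_kmer_db(list(lc), k = 9, neighbors = 0)
  g <- rand_seq(600)
  t1 <- tally_genome(db, g)
  t2 <- tally_genome(db, paste0(g, g))
  merged <- merge(t1, t2, by = c("locus_id", "column"))
  expect_true(all(abs(merged$count.y - 2 * merged$count.x) <= 8 * 2))
})

test_that("a planted microsatellite drives tallies at its alignment columns", {
  set.seed(54)
  flank <- rand_seq(100)
  rep_seq <- paste0(substr(flank, 1, 40), strrep("CAG", 15),
                    substr(flank, 41, 100))
  lc <- aligned_locus("L1", c(r1 = rep_seq))
  db <- build_kmer_db(list(lc), k = 15, neighbors = 0)
  genome <- paste0(rand_seq(200), strrep("CAG", 10000), rand_seq(200))
  tal <- tally_genome(db, genome)
  # columns inside the planted repeat accumulate at least the genomic copy
  # count; flanking columns stay near zero
  rep_cols <- 40:(40 + 45 - 15)
  in_rep <- tal[tal$column %in% rep_cols, ]
  expect_true(all(in_rep$count >= 10000 - 5))
  expect_gt(nrow(in_rep), 0)
})

test_that("high-copy masking uses a strict threshold over any genome", {
  lc <- rand_locus(3, 20)
  tal <- data.frame(genome_id = "g1", locus_id = "L1", column = 5L,
                    count = 100000L)
  expect_false(any(mask_high_copy(lc, tal, threshold = 100000)$mask))
  tal$count <- 100001L
  m <- mask_high_copy(lc, tal, threshold = 100000)
  expect_true(all(m$mask[, 6]))
  expect_equal(sum(m$mask), 3L)

  # over threshold in the second genome only still masks
  tals <- list(data.frame(genome_id = "g1", locus_id = "L1", column = 5L,
                          count = 10L),
               data.frame(genome_id = "g2", locus_id = "L1", column = 5L,
                          count = 200000L))
  expect_true(all(mask_high_copy(lc, tals, threshold = 100000)$mask[, 6]))
})

test_that("probe tiling places starts at the spacing and shifts the final probe", {
  set.seed(55)
  expect_equal(tile_probes(rand_seq(120))$start, 0L)
  expect_equal(tile_probes(rand_seq(150))$start, c(0L, 30L))
  p240 <- tile_probes(rand_seq(240))
  expect_equal(p240$start, c(0L, 30L, 60L, 90L, 120L))
  cov <- integer(240)
  for (s in p240$start) cov[(s + 1):(s + 120)] <- cov[(s + 1):(s + 120)] + 1L
  expect_equal(as.integer(table(cov)), rep(60L, 4))   # ramp up to full density
  # interior bases (>= probe_len from both ends) see exactly density probes
  s420 <- rand_seq(420)
  p420 <- tile_probes(s420)
  cov <- integer(420)
  for (s in p420$start) cov[(s + 1):(s + 120)] <- cov[(s + 1):(s + 120)] + 1L
  expect_true(all(cov[121:300] == 4L))
  expect_true(all(nchar(p420$sequence) == 120L))
  expect_equal(tile_probes(rand_seq(100))$start, integer(0))
})

test_that("probes never overlap masked bases", {
  set.seed(56)
  s <- rand_seq(400)
  mask <- rep(FALSE, 400); mask[200:214] <- TRUE
  p <- tile_probes(s, mask)
  for (st in p$start)
    expect_false(any(mask[(st + 1):(st + 120)]))
  expect_true(nrow(p) < nrow(tile_probes(s)))
})

test_that("replication fills the kit shortest-locus-first and hits capacity exactly", {
  probes <- data.frame(probe_id = c("a", "b", "c"),
                       locus_id = c("L1", "L2", "L3"),
                       reference_taxon = "r", start = 0L,
                       sequence = strrep("A", 120), replicates = 1L,
                       stringsAsFactors = FALSE)
  lens <- c(L1 = 120, L2 = 150, L3 = 240)
  out <- replicate_to_capacity(probes, capacity = 5, locus_lengths = lens)
  expect_equal(setNames(out$replicates, out$probe_id),
               c(a = 2L, b = 2L, c = 1L))
  expect_equal(sum(out$replicates), 5L)

  same <- replicate_to_capacity(probes[1:2, ], capacity = 2,
                                locus_lengths = lens)
  expect_true(all(same$replicates == 1L))

  set.seed(57)
  many <- data.frame(probe_id = sprintf("p%02d", 1:12),
                     locus_id = rep(c("L1", "L2", "L3"), each = 4),
                     reference_taxon = "r",
                     start = rep(c(0L, 30L, 60L, 90L), 3),
                     sequence = strrep("A", 120), replicates = 1L,
                     stringsAsFactors = FALSE)
  out2 <- replicate_to_capacity(many, capacity = 57700, locus_lengths = lens)
  expect_equal(sum(out2$replicates), 57700L)

  expect_error(replicate_to_capacity(many, capacity = 5),
               "exceeds kit capacity")
})
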