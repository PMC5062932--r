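test_that("window identity matches hand values and the brute-force oracle", {
  two <- aligned_locus("L", c(a = strrep("ACGT", 30), b = strrep("ACGT", 30)))
  expect_equal(window_identity(two, 0, 120)$mean_pairwise_identity, 1.0)

  opp <- aligned_locus("L", c(a = strrep("A", 120), b = strrep("C", 120)))
  expect_equal(window_identity(opp, 0, 120)$mean_pairwise_identity, 0.0)

  set.seed(101)
  for (i in 1:25) {
    lc <- rand_locus(sample(3:6, 1), 40, gap_prob = 0.1)
    s <- sample(0:30, 1)
    expect_equal(window_identity(lc, s, 10)$mean_pairwise_identity,
                 oracle_window_identity(lc, s, 10))
  }
  expect_error(window_identity(rand_locus(1, 50), 0, 10), ">= 2 rows")
})

test_that("locus filter enforces the taxon minimum and strict identity threshold", {
  ident6 <- aligned_locus("keep", setNames(rep(strrep("ACGT", 30), 6),
                                           paste0("t", 1:6)))
  expect_length(filter_ortholog_alignments(list(ident6)), 1)

  ident5 <- aligned_locus("drop", setNames(rep(strrep("ACGT", 30), 5),
                                           paste0("t", 1:5)))
  expect_length(filter_ortholog_alignments(list(ident5)), 0)

  # 6 rows (three pairs), cross-pair identity 45/120: mean over the 15
  # pairs is exactly (3*1 + 12*0.375)/15 = 0.5 -> dropped by strict >
  shared <- strrep("A", 45)
  rowA <- paste0(shared, strrep("A", 75))
  rowB <- paste0(shared, strrep("C", 75))
  rowC <- paste0(shared, strrep("G", 75))
  exact_half <- aligned_locus("half", setNames(c(rowA, rowA, rowB, rowB,
                                                 rowC, rowC), paste0("t", 1:6)))
  expect_equal(window_identity(exact_half, 0, 120)$mean_pairwise_identity, 0.5)
  expect_length(filter_ortholog_alignments(list(exact_half)), 0)

  # nudging one cross-pair column to agreement pushes the mean above 0.5
  rowB2 <- paste0(shared, "A", strrep("C", 74))
  rowC2 <- paste0(shared, "A", strrep("G", 74))
  above <- aligned_locus("above", setNames(c(rowA, rowA, rowB2, rowB2,
                                             rowC2, rowC2), paste0("t", 1:6)))
  expect_length(filter_ortholog_alignments(list(above)), 1)

  # monotone: adding an identical row never drops a kept locus
  set.seed(55)
  for (i in 1:10) {
    lc <- rand_locus(6, 150)
    kept <- length(filter_ortholog_alignments(list(lc))) == 1
    bigger <- lc
    bigger$seqs <- rbind(bigger$seqs, bigger$seqs[1, ])
    bigger$mask <- rbind(bigger$mask, bigger$mask[1, ])
    bigger$ids <- c(bigger$ids, "extra"); bigger$taxa <- c(bigger$taxa, "extra")
    kept2 <- length(filter_ortholog_alignments(list(bigger))) == 1
    if (kept) expect_true(kept2)
  }
})

test_that("preliminary target selection honors length, gap and boundary rules", {
  gapfree <- rand_locus(6, 200)
  regs <- select_preliminary_targets(gapfree, min_len = 150)
  expect_equal(regs[, c("start", "end")], data.frame(start = 0L, end = 200L))

  # one gap column splits 260 columns into 100 + 159: only the right side
  # reaches 150
  lc <- rand_locus(6, 260)
  lc$seqs[3, 101] <- "-"
  regs <- select_preliminary_targets(lc, min_len = 150)
  expect_equal(nrow(regs), 1L)
  expect_equal(c(regs$start, regs$end), c(101L, 260L))

  # an exon boundary at 150 splits 300 gap-free columns into two targets
  lc300 <- rand_locus(6, 300)
  regs <- select_preliminary_targets(lc300, boundaries = 150L, min_len = 150)
  expect_equal(regs$start, c(0L, 150L))
  expect_equal(regs$end, c(150L, 300L))

  # property: intervals are disjoint, >= min_len, gap- and boundary-free
  set.seed(202)
  for (i in 1:20) {
    lc <- rand_locus(6, 400, gap_prob = 0.002)
    b <- sort(sample(50:350, sample(0:2, 1)))
    regs <- select_preliminary_targets(lc, boundaries = b, min_len = 150)
    if (nrow(regs) >= 2)
      expect_true(all(regs$start[-1] >= head(regs$end, -1)))
    for (j in seq_len(nrow(regs))) {
      expect_gte(regs$length[j], 150)
      sub <- lc$seqs[, (regs$start[j] + 1):regs$end[j], drop = FALSE]
      expect_false(any(sub == "-"))
      expect_false(any(b > regs$start[j] & b < regs$end[j]))
    }
  }
})

test_that("alignments split at boundaries and reassemble to the parent", {
  lc <- rand_locus(4, 400)
  expect_equal(n_cols(split_alignment_at_boundaries(lc, integer(0))[[1]]), 400)

  kids <- split_alignment_at_boundaries(lc, c(100L, 250L))
  expect_equal(vapply(kids, n_cols, integer(1)), c(100L, 150L, 150L))
  expect_equal(vapply(kids, `[[`, character(1), "locus_id"),
               paste0("L1_e", 1:3))

  set.seed(9)
  for (i in 1:10) {
    lc <- rand_locus(3, sample(100:300, 1))
    b <- sort(sample(seq_len(n_cols(lc) - 1), sample(1:4, 1)))
    kids <- split_alignment_at_boundaries(lc, b)
    glued <- do.call(cbind, lapply(kids, `[[`, "seqs"))
    expect_identical(glued, lc$seqs)
  }
  expect_error(split_alignment_at_boundaries(lc, n_cols(lc)), "boundary")
})
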