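test_that("concatenation lays out blocks and missing-fills absent taxa", {
  l1 <- aligned_locus("L1", setNames(c("ACG", "ACT"), c("x1", "x2")),
                      taxa = c("A", "B"))
  l2 <- aligned_locus("L2", setNames(c("TTTT", "GGGG"), c("y1", "y2")),
                      taxa = c("A", "C"))
  sm <- concatenate(list(l1, l2))
  expect_equal(dim(sm$mat), c(3L, 7L))
  expect_equal(paste(sm$mat["B", ], collapse = ""), "ACT????")
  expect_equal(paste(sm$mat["C", ], collapse = ""), "???GGGG")
  expect_equal(sm$partitions$end, c(3L, 7L))

  single <- concatenate(list(l1))
  expect_identical(single$mat[c("A", "B"), ], l1$seqs,
                   ignore_attr = TRUE)

  dup <- aligned_locus("L3", setNames(c("AA", "CC"), c("z1", "z2")),
                       taxa = c("A", "A"))
  expect_error(concatenate(list(dup)), "duplicate taxon")
})

test_that("site classes are counted like the brute-force scanner", {
  m <- rbind(A = c("A", "A", "A"), B = c("A", "A", "A"),
             C = c("A", "A", "T"), D = c("A", "T", "T"))
  expect_equal(unname(count_site_classes(m)), c(2L, 1L))  # AAAT variable only; AATT informative

  set.seed(81)
  for (i in 1:20) {
    mat <- matrix(sample(c(BASES, "-", "N", "?"), 10 * 100, replace = TRUE,
                         prob = c(rep(0.2, 4), 0.1, 0.05, 0.05)),
                  nrow = 10)
    got <- count_site_classes(mat)
    want <- oracle_site_classes(mat)
    expect_equal(unname(got), want)
    expect_lte(got["n_informative"], got["n_variable"])
  }
})

test_that("missingness is the missing-cell percentage", {
  full <- matrix("A", 4, 5)
  expect_equal(missingness(full), 0)
  onemiss <- matrix(c("A", "A", "A", "-"), 2, 2)
  expect_equal(missingness(onemiss), 25)
  set.seed(82)
  mat <- matrix(sample(c(BASES, "-", "N", "?"), 600, replace = TRUE), 20)
  expect_equal(missingness(mat),
               100 * sum(mat %in% c("-", "N", "?")) / 600)
})

test_that("PIC profiles count loci per offset from the anchor center", {
  l <- aligned_locus("L1", setNames(c("AAAAA", "AAAAA", "ATAAA", "ATAAA"),
                                    sprintf("s%d", 1:4)),
                     taxa = sprintf("t%d", 1:4),
                     meta = list(anchor_center = 2))
  prof <- pic_by_position(list(l))
  expect_equal(prof$offset, -2:2)
  expect_equal(prof$n_loci_present, rep(1L, 5))
  expect_equal(prof$n_loci_with_pic[prof$offset == -1], 1L)
  expect_equal(sum(prof$n_loci_with_pic), 1L)

  set.seed(83)
  loci <- lapply(1:5, function(i)
    rand_locus(6, sample(c(11, 21, 31), 1), locus_id = sprintf("L%d", i)))
  prof <- pic_by_position(loci)
  # occupancy at offset 0 equals the locus count; totals match a direct tally
  expect_equal(prof$n_loci_present[prof$offset == 0], 5L)
  direct <- 0L
  for (lc in loci) {
    cls <- apply(lc$seqs, 2, function(col) {
      tab <- table(col[!(col %in% c("-", "N", "?"))]); sum(tab >= 2) >= 2
    })
    center <- (n_cols(lc) - 1) / 2
    if (cls[center + 1]) direct <- direct + 1L
  }
  expect_equal(prof$n_loci_with_pic[prof$offset == 0], direct)
})

test_that("the PIC-length regression matches closed-form least squares", {
  # proportional counts give a perfect fit
  st <- data.frame(length = c(100, 200, 300, 400), n_informative = c(10, 20, 30, 40))
  fit <- suppressWarnings(pic_length_regression(st))  # "essentially perfect fit"
  expect_equal(fit$adjusted_r_squared, 1.0)
  expect_equal(fit$slope, 0.1)

  # hand dataset vs closed-form OLS
  st5 <- data.frame(length = c(120, 250, 310, 480, 650),
                    n_informative = c(8, 30, 25, 60, 81))
  fit5 <- pic_length_regression(st5)
  x <- st5$length; y <- st5$n_informative
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(fit5$slope, beta)
  expect_equal(fit5$intercept, alpha)
  r2 <- 1 - sum((y - alpha - beta * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit5$adjusted_r_squared, 1 - (1 - r2) * (5 - 1) / (5 - 2))

  # permuted counts carry no signal
  set.seed(84)
  stp <- data.frame(length = sample(100:2000, 500, replace = TRUE))
  stp$n_informative <- sample(stp$length)  # break the pairing
  fitp <- pic_length_regression(stp)
  expect_lt(abs(fitp$adjusted_r_squared), 0.1)

  expect_error(pic_length_regression(st5[1:2, ]), ">= 3 loci")
  same <- data.frame(length = rep(100, 5), n_informative = 1:5)
  expect_error(pic_length_regression(same), "zero variance")
})
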