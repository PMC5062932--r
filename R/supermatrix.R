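# Supermatrix construction and informativeness statistics: concatenation
# with per-locus partitions, site classification, missingness, parsimony-
# informative-character (PIC) profiles and the PIC-vs-length regression.

MISSING_CHARS <- c("-", "N", "?")

#' Concatenate loci into a partitioned supermatrix
#'
#' Loci are laid out in list order as contiguous column blocks; a taxon
#' absent from a locus is filled with the missing symbol `?` across that
#' block. Masked cells are written as `N`.
#'
#' @param loci list of `aligned_locus` (taxon labels unique within each
#'   locus); zero-width loci are dropped.
#' @param taxon_universe optional ordered character vector of taxa (default:
#'   union of locus taxa, sorted).
#' @return a `supermatrix`: `list(taxa, mat, partitions, locus_ids)` where
#'   `mat` is a taxa x columns character matrix and `partitions` is a
#'   1-based inclusive [partition_table()].
#' @export
concatenate <- function(loci, taxon_universe = NULL) {
  loci <- Filter(function(lc) n_cols(lc) > 0, loci)
  if (length(loci) == 0) stop("no non-empty loci to concatenate")
  for (lc in loci) {
    if (anyDuplicated(lc$taxa))
      stop("duplicate taxon within locus ", lc$locus_id, ": ",
           paste(unique(lc$taxa[duplicated(lc$taxa)]), collapse = ", "))
  }
  taxa <- taxon_universe %||% sort(unique(unlist(lapply(loci, `[[`, "taxa"))))
  widths <- vapply(loci, n_cols, integer(1))
  names(widths) <- vapply(loci, `[[`, character(1), "locus_id")
  parts <- partition_table(widths)
  mat <- matrix("?", length(taxa), sum(widths),
                dimnames = list(taxa, NULL))
  for (i in seq_along(loci)) {
    lc <- loci[[i]]
    if (!all(lc$taxa %in% taxa))
      stop("locus ", lc$locus_id, " has taxa outside the taxon universe")
    block <- lc$seqs
    block[lc$mask] <- "N"
    cols <- seq(parts$start[i], parts$end[i])
    mat[lc$taxa, cols] <- block
  }
  structure(list(taxa = taxa, mat = mat, partitions = parts,
                 locus_ids = names(widths)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$taxa), " taxa x ", ncol(x$mat), " columns, ",
      nrow(x$partitions), " partition(s)\n", sep = "")
  invisible(x)
}

# Per-column site class over unambiguous bases (gap/N/? excluded).
classify_column <- function(col) {
  bases <- col[!(col %in% MISSING_CHARS)]
  if (length(bases) == 0) return(c(variable = FALSE, informative = FALSE))
  tab <- table(bases)
  c(variable = length(tab) >= 2,
    informative = sum(tab >= 2) >= 2)
}

#' Count variable and parsimony-informative sites
#'
#' A column is variable when it holds at least two distinct unambiguous
#' bases; parsimony-informative when at least two distinct bases each occur
#' at least twice. Gaps, `N` and `?` are excluded from the tally.
#'
#' @param mat character matrix (taxa x columns) or a `supermatrix`.
#' @return `c(n_variable, n_informative)`.
#' @export
count_site_classes <- function(mat) {
  if (inherits(mat, "supermatrix")) mat <- mat$mat
  if (ncol(mat) == 0) return(c(n_variable = 0L, n_informative = 0L))
  cls <- apply(mat, 2, classify_column)
  c(n_variable = sum(cls["variable", ]),
    n_informative = sum(cls["informative", ]))
}

#' Percent missing characters
#'
#' @param mat character matrix or `supermatrix`.
#' @param missing characters counted as missing (gap, `N`, absent-taxon
#'   fill `?`).
#' @return percentage in `[0, 100]`.
#' @export
missingness <- function(mat, missing = MISSING_CHARS) {
  if (inherits(mat, "supermatrix")) mat <- mat$mat
  100 * sum(mat %in% missing) / length(mat)
}

#' Per-locus alignment statistics
#'
#' @param loci list of `aligned_locus`.
#' @return data.frame (`locus_id`, `length`, `n_taxa`, `n_variable`,
#'   `n_informative`, `pct_missing`).
#' @export
per_locus_stats <- function(loci) {
  do.call(rbind, lapply(loci, function(lc) {
    m <- lc$seqs
    m[lc$mask] <- "N"
    cls <- count_site_classes(m)
    data.frame(locus_id = lc$locus_id, length = ncol(m), n_taxa = nrow(m),
               n_variable = unname(cls["n_variable"]),
               n_informative = unname(cls["n_informative"]),
               pct_missing = missingness(m), stringsAsFactors = FALSE)
  }))
}

#' Dataset-level supermatrix statistics
#'
#' @param matrix a `supermatrix`.
#' @return one-row data.frame (`n_loci`, `n_taxa`, `total_bp`,
#'   `n_variable_sites`, `n_informative_sites`, `pct_missing`).
#' @export
matrix_stats <- function(matrix) {
  cls <- count_site_classes(matrix)
  data.frame(n_loci = nrow(matrix$partitions), n_taxa = length(matrix$taxa),
             total_bp = ncol(matrix$mat),
             n_variable_sites = unname(cls["n_variable"]),
             n_informative_sites = unname(cls["n_informative"]),
             pct_missing = missingness(matrix), stringsAsFactors = FALSE)
}

#' PIC occupancy profile relative to the anchor center
#'
#' For each nucleotide offset from the anchor center, counts (a) the number
#' of loci with at least one parsimony-informative column at that offset
#' and (b) the number of loci having any character there.
#'
#' @param loci list of `aligned_locus`.
#' @param anchor_centers optional named numeric vector of 0-based center
#'   columns per locus; defaults to each locus's `meta$anchor_center`, then
#'   to its midpoint.
#' @return data.frame (`offset`, `n_loci_with_pic`, `n_loci_present`).
#' @export
pic_by_position <- function(loci, anchor_centers = NULL) {
  rows <- list()
  for (lc in loci) {
    if (n_cols(lc) == 0) next
    center <- if (!is.null(anchor_centers) && lc$locus_id %in% names(anchor_centers))
      anchor_centers[[lc$locus_id]]
    else lc$meta$anchor_center %||% ((n_cols(lc) - 1) / 2)
    m <- lc$seqs
    m[lc$mask] <- "N"
    cls <- apply(m, 2, classify_column)
    present <- apply(m, 2, function(col) any(!(col %in% MISSING_CHARS)))
    offs <- round(seq_len(ncol(m)) - 1 - center)
    rows[[length(rows) + 1L]] <-
      data.frame(offset = offs, pic = cls["informative", ], present = present)
  }
  if (length(rows) == 0)
    return(data.frame(offset = integer(0), n_loci_with_pic = integer(0),
                      n_loci_present = integer(0)))
  all <- do.call(rbind, rows)
  agg <- aggregate(cbind(pic, present) ~ offset, data = all, FUN = sum)
  data.frame(offset = agg$offset, n_loci_with_pic = agg$pic,
             n_loci_present = agg$present)
}

#' Regression of per-locus PIC count on locus length
#'
#' Ordinary least squares of the number of parsimony-informative characters
#' on alignment length, reporting the slope, intercept, adjusted R-squared
#' and the two-sided t-test p-value of the slope.
#'
#' @param stats data.frame from [per_locus_stats()] (needs `length` and
#'   `n_informative`), with at least 3 loci.
#' @return `list(slope, intercept, adjusted_r_squared, p_value)`.
#' @export
pic_length_regression <- function(stats) {
  if (nrow(stats) < 3) stop("need >= 3 loci for the regression")
  if (stats::var(stats$length) == 0) stop("zero variance in locus length")
  fit <- lm(n_informative ~ length, data = stats)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       adjusted_r_squared = s$adj.r.squared,
       p_value = s$coefficients["length", "Pr(>|t|)"])
}
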