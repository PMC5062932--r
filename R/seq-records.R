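# Sequence records: the flat container shared by every stage.
#
# A set of records is a data.frame with columns
#   id           unique sequence identifier (FASTA header word)
#   taxon        species label
#   sample       specimen label (equals taxon when no map is supplied)
#   sequence     uppercase string over {A,C,G,T,N,-}
#   read_support integer count of supporting reads, or NA when absent

#' Construct a set of sequence records
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of sequences (normalized to `{A,C,G,T,N,-}`).
#' @param taxon species labels; defaults to [parse_taxon()] of `id`.
#' @param sample specimen labels; defaults to `id`.
#' @param read_support integer supporting-read counts, `NA` when absent.
#' @return a `data.frame` of class `seq_records`.
#' @export
seq_records <- function(id, sequence, taxon = parse_taxon(id), sample = id,
                        read_support = NA_integer_) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) stop("duplicate record ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- normalize_sequence(sequence)
  if (any(nchar(sequence) == 0)) stop("empty sequence for id ",
                                      id[which(nchar(sequence) == 0)[1]])
  rs <- suppressWarnings(as.integer(read_support))
  if (any(!is.na(rs) & rs < 0)) stop("read_support must be >= 0")
  out <- data.frame(id = as.character(id), taxon = as.character(taxon),
                    sample = as.character(sample), sequence = sequence,
                    read_support = rep_len(rs, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Derive a species label from a specimen identifier
#'
#' Specimen IDs in capture projects usually encode specimen, not species
#' (e.g. `APH_0856`). By default the taxon is the identifier prefix up to the
#' first underscore-delimited all-numeric token (`APH_0856` -> `APH`); supply
#' an explicit sample map via [read_sample_map()] / [apply_sample_map()] for
#' real species assignments.
#'
#' @param id character vector of identifiers.
#' @return character vector of taxon labels.
#' @export
parse_taxon <- function(id) {
  vapply(strsplit(as.character(id), "_"), function(parts) {
    num <- grepl("^[0-9]+$", parts)
    if (any(num)) {
      keep <- seq_len(which(num)[1] - 1L)
      if (length(keep) == 0) return(parts[1])
      paste(parts[keep], collapse = "_")
    } else parts[1]
  }, character(1))
}

#' Read a sample-to-taxon map
#'
#' A two-column TSV (`sample`, `taxon`) mapping specimen labels to species.
#'
#' @param path TSV file with header columns `sample` and `taxon`.
#' @return named character vector, names = sample, values = taxon.
#' @export
read_sample_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "taxon") %in% names(tab)))
    stop("sample map must have columns 'sample' and 'taxon'")
  setNames(as.character(tab$taxon), as.character(tab$sample))
}

#' Apply a sample map to records
#'
#' @param records a `seq_records` data.frame.
#' @param map named character vector from [read_sample_map()].
#' @return records with `taxon` replaced where the sample is mapped.
#' @export
apply_sample_map <- function(records, map) {
  hit <- records$sample %in% names(map)
  records$taxon[hit] <- unname(map[records$sample[hit]])
  records
}

#' @export
print.seq_records <- function(x, ...) {
  cat("<seq_records> ", nrow(x), " record(s), ",
      length(unique(x$taxon)), " taxa\n", sep = "")
  if (nrow(x)) {
    show <- utils::head(x, 5)
    show$sequence <- paste0(substr(show$sequence, 1, 40),
                            ifelse(nchar(show$sequence) > 40, "...", ""))
    print.data.frame(show, row.names = FALSE)
    if (nrow(x) > 5) cat("... and ", nrow(x) - 5, " more\n", sep = "")
  }
  invisible(x)
}
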