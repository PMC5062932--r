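# FASTA reading/writing with read-support metadata in the header.
#
# Consensus assemblies carry the number of supporting reads as a `reads=N`
# token in the description; round-tripping preserves it.

#' Read a FASTA file into sequence records
#'
#' Sequences are uppercased and normalized to `{A,C,G,T,N,-}`. A `reads=N`
#' token anywhere in the description line is parsed into `read_support`.
#'
#' @param path FASTA file.
#' @param sample_map optional named vector (see [read_sample_map()]) mapping
#'   sample to taxon; otherwise taxa are derived with [parse_taxon()].
#' @return a `seq_records` data.frame (zero rows for an empty file).
#' @export
read_fasta <- function(path, sample_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(seq_records(character(0), character(0)))
  is_header <- startsWith(trimws(lines), ">")
  if (!is_header[nonblank[1]])
    stop("FASTA parse error at line ", nonblank[1], ": expected '>' header")
  hdr_idx <- which(is_header)
  bounds <- c(hdr_idx, length(lines) + 1L)
  headers <- sub("^>", "", trimws(lines[hdr_idx]))
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  if (any(!nzchar(ids))) {
    bad <- hdr_idx[!nzchar(ids)][1]
    stop("FASTA parse error at line ", bad, ": empty header")
  }
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    body <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[!startsWith(trimws(body), ">")]
    paste(gsub("\\s", "", body), collapse = "")
  }, character(1))
  if (any(nchar(seqs) == 0)) {
    bad <- which(nchar(seqs) == 0)[1]
    stop("FASTA parse error at line ", hdr_idx[bad], ": record '", ids[bad],
         "' has an empty sequence")
  }
  support <- rep(NA_integer_, length(headers))
  m <- regmatches(headers, regexpr("\\breads=[0-9]+\\b", headers))
  has <- grepl("\\breads=[0-9]+\\b", headers)
  support[has] <- as.integer(sub("reads=", "", m))
  rec <- seq_records(ids, seqs, read_support = support)
  if (!is.null(sample_map)) rec <- apply_sample_map(rec, sample_map)
  rec
}

#' Write sequence records to FASTA
#'
#' Round-trips with [read_fasta()] on `(id, sequence, read_support)`:
#' records with a read count are written with a `reads=N` header token.
#'
#' @param records a `seq_records` data.frame.
#' @param path output file.
#' @param width line-wrap width (0 = no wrapping).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.na(records$read_support[i]))
      hdr <- paste0(hdr, " reads=", records$read_support[i])
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    if (width > 0 && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      s <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    }
    writeLines(s, con)
  }
  invisible(path)
}
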