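# FASTQ I/O. Reads are carried as a plain data.frame ("read table") with
# columns read_id, sequence, qualities (Phred+33 string), description —
# convenient for the string slicing extraction does. Parsing and writing go
# through Biostrings, which also handles gzip transparently.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return data.frame with columns `read_id`, `sequence`, `qualities`
#'   (Phred+33 string), `description` (full header text after the id, `NA` if
#'   none).
#' @export
read_fastq <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  headers <- names(seqs)
  if (is.null(headers)) headers <- character(length(seqs))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers),
                 NA_character_)
  quals <- as.character(S4Vectors::mcols(seqs)$qualities)
  if (length(seqs) == 0) quals <- character(0)
  out <- data.frame(read_id = ids, sequence = as.character(seqs),
                    qualities = quals, description = desc,
                    stringsAsFactors = FALSE, row.names = NULL)
  bad <- nchar(out$sequence) != nchar(out$qualities)
  if (any(bad)) {
    stop("malformed FASTQ record(s): sequence/quality length mismatch for ",
         paste(utils::head(out$read_id[bad], 5), collapse = ", "))
  }
  out
}

#' Write a read table to FASTQ
#'
#' @param reads read table as returned by [read_fastq()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  headers <- ifelse(is.na(reads$description), reads$read_id,
                    paste(reads$read_id, reads$description))
  if (nrow(reads) == 0) {
    con <- open_out(path); close(con)  # valid empty FASTQ
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(
    seqs, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qualities),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

# Contract checks for an in-memory read table; names the first offender.
validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "qualities") %in% names(reads)))
  bad <- nchar(reads$sequence) != nchar(reads$qualities)
  if (any(bad)) {
    stop("read '", reads$read_id[which(bad)[1]],
         "': sequence/quality length mismatch")
  }
  invisible(reads)
}

#' Filter reads on mean base quality and length
#'
#' A minimal stand-in for the quality/length read filter run ahead of barcode
#' detection in long-read single-cell pipelines.
#'
#' @param reads read table ([read_fastq()]).
#' @param min_mean_quality minimum mean Phred quality (0 disables).
#' @param min_length,max_length inclusive length bounds.
#' @return list with `kept` (read table, input order preserved) and
#'   `n_dropped`.
#' @export
filter_reads <- function(reads, min_mean_quality = 0, min_length = 1L,
                         max_length = .Machine$integer.max) {
  stopifnot(min_mean_quality >= 0, min_length >= 0, max_length >= min_length)
  validate_reads(reads)
  len <- nchar(reads$sequence)
  meanq <- vapply(reads$qualities,
                  function(q) if (nzchar(q)) mean(phred_decode(q)) else 0,
                  numeric(1), USE.NAMES = FALSE)
  keep <- len >= min_length & len <= max_length & meanq >= min_mean_quality
  list(kept = reads[keep, , drop = FALSE],
       n_dropped = sum(!keep))
}
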