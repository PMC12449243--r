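# Join barcode-correction results onto aligned reads (CR/CB/UR/CY/UY tags)
# and split alignment files for embarrassingly parallel deduplication.

#' Tag aligned reads with barcode and UMI information
#'
#' Joins the corrected barcode table onto alignments by read id and writes
#' the standard five tags: `CR` (raw barcode), `CB` (corrected barcode, only
#' for rows with status `exact`/`corrected`), `UR` (raw UMI), `CY`/`UY`
#' (Phred+33 quality strings). Secondary and supplementary alignments of a
#' read receive the same tag set as its primary.
#'
#' @param bam_in SAM/BAM path or a `sam_set`.
#' @param corrected_table corrected barcode table (data.frame or CSV path)
#'   with the [correct_table()] columns.
#' @param out optional output SAM/BAM path.
#' @param drop_uncorrected drop records that did not receive a `CB` tag.
#' @param strict error (rather than count) when an aligned read id is absent
#'   from the table.
#' @return list with `sam` (tagged `sam_set`), `out` (path or `NULL`) and
#'   `stats` (`n_records`, `n_tagged`, `n_with_CB`, `n_dropped`).
#' @export
tag_bam <- function(bam_in, corrected_table, out = NULL,
                    drop_uncorrected = FALSE, strict = FALSE) {
  sam <- if (is.character(bam_in)) read_sam(bam_in) else bam_in
  tab <- if (is.character(corrected_table)) read_barcode_table(corrected_table)
         else corrected_table
  need <- c("read_id", "barcode", "barcode_quals", "umi", "umi_quals", "status")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("corrected table missing column(s): ",
                         paste(miss, collapse = ", "))
  rec <- sam$records
  m <- match(rec$qname, tab$read_id)
  if (strict && anyNA(m)) {
    stop("aligned read id(s) absent from table: ",
         paste(utils::head(unique(rec$qname[is.na(m)]), 10), collapse = ", "))
  }
  hit <- !is.na(m)
  tags <- rec$tags
  tags[hit] <- sam_set_tag(tags[hit], "CR", tab$barcode[m[hit]])
  tags[hit] <- sam_set_tag(tags[hit], "CY", tab$barcode_quals[m[hit]])
  tags[hit] <- sam_set_tag(tags[hit], "UR", tab$umi[m[hit]])
  tags[hit] <- sam_set_tag(tags[hit], "UY", tab$umi_quals[m[hit]])
  has_cb <- hit & tab$status[m] %in% c("exact", "corrected") &
    !is.na(ifelse(hit, tab$corrected_barcode[m], NA))
  tags[has_cb] <- sam_set_tag(tags[has_cb], "CB",
                              tab$corrected_barcode[m[has_cb]])
  rec$tags <- tags
  n_dropped <- 0L
  if (drop_uncorrected) {
    n_dropped <- sum(!has_cb)
    rec <- rec[has_cb, , drop = FALSE]
  }
  out_sam <- structure(list(header = sam$header, records = rec),
                       class = "sam_set")
  if (!is.null(out)) write_sam(out_sam, out)
  list(sam = out_sam, out = out,
       stats = list(n_records = nrow(sam$records),
                    n_tagged = sum(hit),
                    n_with_CB = sum(has_cb),
                    n_dropped = n_dropped))
}

#' Split alignments by chromosome
#'
#' @param bam_in SAM/BAM path or `sam_set`.
#' @param out_dir output directory; one SAM per contig plus an `unmapped`
#'   bucket when unmapped records exist. Set to `NULL` to return in-memory
#'   `sam_set`s only.
#' @return named list (contig -> path, or contig -> `sam_set` when
#'   `out_dir` is `NULL`); record counts across outputs sum to the input.
#' @export
split_by_chromosome <- function(bam_in, out_dir = NULL) {
  sam <- if (is.character(bam_in)) read_sam(bam_in) else bam_in
  rec <- sam$records
  group <- ifelse(flag_is_unmapped(rec$flag) | rec$rname == "*",
                  "unmapped", rec$rname)
  split_and_emit(sam, rec, group, out_dir)
}

#' Split transcriptome alignments by the chromosome of their transcript
#'
#' @param bam_in SAM/BAM path or `sam_set` aligned to transcript references.
#' @param tx2chrom named character vector, transcript id -> chromosome.
#' @param out_dir as in [split_by_chromosome()].
#' @param strict error on transcripts missing from `tx2chrom` instead of
#'   routing them to an `unassigned` bucket.
#' @return named list as in [split_by_chromosome()].
#' @export
split_by_feature_groups <- function(bam_in, tx2chrom, out_dir = NULL,
                                    strict = FALSE) {
  sam <- if (is.character(bam_in)) read_sam(bam_in) else bam_in
  rec <- sam$records
  unmapped <- flag_is_unmapped(rec$flag) | rec$rname == "*"
  group <- unname(tx2chrom[rec$rname])
  if (strict) {
    bad <- unique(rec$rname[is.na(group) & !unmapped])
    if (length(bad)) stop("transcript(s) absent from tx2chrom: ",
                          paste(utils::head(bad, 10), collapse = ", "))
  }
  group[is.na(group)] <- "unassigned"
  group[unmapped] <- "unmapped"
  split_and_emit(sam, rec, group, out_dir)
}

split_and_emit <- function(sam, rec, group, out_dir) {
  idx <- split(seq_len(nrow(rec)), group)
  out <- lapply(idx, function(i) {
    structure(list(header = sam$header, records = rec[i, , drop = FALSE]),
              class = "sam_set")
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(out), function(g) {
      p <- file.path(out_dir, paste0(g, ".sam"))
      write_sam(out[[g]], p)
      p
    }, character(1))
    return(as.list(paths))
  }
  out
}
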