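# Multi-stage QC tracking: a small store of per-sample read counts across
# the pipeline funnel, the summary CSV, per-cell metrics from a count
# matrix, and flag-based mapping counts.

#' The tracked pipeline stages, in funnel order
#' @export
QC_STAGES <- c("raw", "trimmed", "structured", "aligned", "primary_mapped",
               "cb_tagged", "deduplicated")

#' Create an empty stage-count store
#'
#' @return data.frame of class `stage_store` with columns `sample`, `stage`,
#'   `n_reads`.
#' @export
stage_store <- function() {
  structure(data.frame(sample = character(0), stage = character(0),
                       n_reads = integer(0), stringsAsFactors = FALSE),
            class = c("stage_store", "data.frame"))
}

#' Record a read count for one (sample, stage)
#'
#' Idempotent upsert: re-recording the same key replaces the count.
#'
#' @param store a [stage_store()].
#' @param sample sample name.
#' @param stage one of [QC_STAGES].
#' @param n non-negative read count.
#' @return the updated store.
#' @export
record_stage <- function(store, sample, stage, n) {
  if (!stage %in% QC_STAGES) {
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(QC_STAGES, collapse = ", "))
  }
  if (is.na(n) || n < 0) stop("n_reads must be non-negative")
  hit <- store$sample == sample & store$stage == stage
  if (any(hit)) {
    store$n_reads[hit] <- as.integer(n)
  } else {
    store <- structure(
      rbind(store, data.frame(sample = sample, stage = stage,
                              n_reads = as.integer(n),
                              stringsAsFactors = FALSE)),
      class = c("stage_store", "data.frame"))
  }
  store
}

#' Write the tracking summary CSV
#'
#' One row per sample, one column per stage in funnel order; stages never
#' recorded are left blank.
#'
#' @param store a [stage_store()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
emit_tracking_csv <- function(store, path) {
  samples <- unique(store$sample)
  wide <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (st in QC_STAGES) {
    m <- match(paste(samples, st), paste(store$sample, store$stage))
    wide[[st]] <- store$n_reads[m]
  }
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tracking CSV back into a stage store
#'
#' @param path CSV written by [emit_tracking_csv()].
#' @return a [stage_store()] (blank cells dropped).
#' @export
read_tracking_csv <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  store <- stage_store()
  for (i in seq_len(nrow(wide))) {
    for (st in intersect(QC_STAGES, names(wide))) {
      n <- wide[[st]][i]
      if (!is.na(n)) store <- record_stage(store, wide$sample[i], st, n)
    }
  }
  store
}

#' Assert the monotone pipeline funnel on a store
#'
#' Within each sample, read counts must be non-increasing along
#' structured -> cb_tagged -> deduplicated.
#'
#' @param store a [stage_store()].
#' @return `TRUE` invisibly, or an error naming the violating sample.
#' @export
check_funnel <- function(store) {
  funnel <- c("structured", "cb_tagged", "deduplicated")
  for (s in unique(store$sample)) {
    n <- vapply(funnel, function(st) {
      hit <- store$sample == s & store$stage == st
      if (any(hit)) store$n_reads[hit][1] else NA_integer_
    }, integer(1))
    n <- n[!is.na(n)]
    if (length(n) > 1 && any(diff(n) > 0)) {
      stop("funnel violation for sample '", s, "': ",
           paste(n, collapse = " -> "))
    }
  }
  invisible(TRUE)
}

#' Per-cell metrics from a count matrix
#'
#' `nCount` is the column mass per barcode, `nFeature` the number of
#' features with non-zero count; cells are barcodes with non-zero mass.
#'
#' @param cm a `count_matrix`.
#' @return list of class `cell_metrics`: `n_cells`, `mean_reads_per_cell`,
#'   `median_ncount`, `median_nfeature`, plus per-cell vectors `ncount` and
#'   `nfeature`. An empty matrix yields `n_cells = 0` and `NA` medians.
#' @export
cell_metrics <- function(cm) {
  ncount <- Matrix::colSums(cm$matrix)
  nfeature <- Matrix::colSums(cm$matrix > 0)
  cells <- ncount > 0
  out <- list(
    n_cells = sum(cells),
    mean_reads_per_cell = if (any(cells)) sum(ncount) / sum(cells) else NA_real_,
    median_ncount = if (any(cells)) stats::median(ncount[cells]) else NA_real_,
    median_nfeature = if (any(cells)) stats::median(nfeature[cells]) else NA_real_,
    ncount = ncount[cells],
    nfeature = nfeature[cells])
  structure(out, class = "cell_metrics")
}

#' @export
print.cell_metrics <- function(x, ...) {
  cat(sprintf(
    "<cell_metrics> %d cell%s; mean reads/cell %.2f; median nCount %s; median nFeature %s\n",
    x$n_cells, if (x$n_cells == 1) "" else "s", x$mean_reads_per_cell,
    format(x$median_ncount), format(x$median_nfeature)))
  invisible(x)
}

#' Flag-based mapping summary of an alignment file
#'
#' @param bam_in SAM/BAM path or `sam_set`.
#' @return list `n_records`, `n_primary`, `n_mapped`, `n_cb_tagged`.
#' @export
mapping_summary <- function(bam_in) {
  sam <- if (is.character(bam_in)) read_sam(bam_in) else bam_in
  rec <- sam$records
  list(n_records = nrow(rec),
       n_primary = sum(flag_is_primary(rec$flag)),
       n_mapped = sum(!flag_is_unmapped(rec$flag)),
       n_cb_tagged = sum(!is.na(sam_get_tag(rec$tags, "CB"))))
}
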