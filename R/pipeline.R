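# End-to-end driver: extract -> whitelist -> correct -> tag -> dedup ->
# count -> QC, over a FASTQ plus an externally aligned SAM/BAM. Used by the
# worked examples and by end-to-end recovery tests; each stage is also
# callable on its own.

#' Run the full secondary-analysis pipeline
#'
#' @param fastq input FASTQ of raw long reads.
#' @param alignments coordinate-sorted SAM/BAM (or `sam_set`) from an
#'   external aligner; genome-aligned for `mode = "genome"`,
#'   transcriptome-aligned for `mode = "transcriptome"`.
#' @param annotation [load_annotation()] result or GTF path (required in
#'   genome mode; in transcriptome mode used for `tx2gene` when given).
#' @param out_dir output directory (barcode-free FASTQ, tables, tagged and
#'   deduplicated SAM, count matrix, tracking CSV).
#' @param chem a [chemistry_profile()].
#' @param mode `"genome"` or `"transcriptome"`.
#' @param expected_cells expected cell count for whitelist thresholding;
#'   `NULL` uses knee detection.
#' @param whitelist optional precomputed whitelist (data.frame or path),
#'   skipping ranking/knee.
#' @param correction a [correction_params()].
#' @param dedup_method `"directional"` or `"unique"`.
#' @param sample sample name used in the tracking CSV.
#' @param min_mean_quality,min_length,max_length optional read filter.
#' @return list with `whitelist`, `corrected` ([correct_table()] result),
#'   `tag_stats`, `dedup_stats`, `matrix` (a `count_matrix`), `count_stats`,
#'   `metrics` ([cell_metrics()]), `tracking` (a [stage_store()]) and
#'   `paths`.
#' @export
run_pipeline <- function(fastq, alignments, annotation = NULL,
                         out_dir = tempfile("ontcells_"),
                         chem = get_chemistry("10x-3p-v3"),
                         mode = c("genome", "transcriptome"),
                         expected_cells = NULL, whitelist = NULL,
                         correction = correction_params(),
                         dedup_method = "directional",
                         sample = "sample1",
                         min_mean_quality = 0, min_length = 1L,
                         max_length = .Machine$integer.max) {
  mode <- match.arg(mode)
  if (mode == "genome" && is.null(annotation)) {
    stop("genome mode requires an annotation (GTF)")
  }
  if (is.character(annotation)) annotation <- load_annotation(annotation)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fastq = file.path(out_dir, "trimmed.fastq"),
                table = file.path(out_dir, "barcodes.csv"),
                corrected = file.path(out_dir, "barcodes_corrected.csv"),
                whitelist = file.path(out_dir, "whitelist.txt"),
                tagged = file.path(out_dir, "tagged.sam"),
                dedup = file.path(out_dir, "dedup.sam"),
                matrix = file.path(out_dir, "counts"),
                tracking = file.path(out_dir, "tracking.csv"))
  ex <- extract_batch(fastq, chem, paths$fastq, paths$table,
                      min_mean_quality = min_mean_quality,
                      min_length = min_length, max_length = max_length)
  tab <- read_barcode_table(paths$table)
  if (is.null(whitelist)) {
    ranked <- rank_barcodes(tab, correction$min_whitelist_quality)
    wl <- build_whitelist(ranked, expected_cells)
  } else {
    wl <- if (is.character(whitelist)) read_whitelist(whitelist) else whitelist
  }
  write_whitelist(wl, paths$whitelist)
  corr <- correct_table(tab, wl, correction, out_table = paths$corrected)

  sam <- if (is.character(alignments)) read_sam(alignments) else alignments
  tg <- tag_bam(sam, corr$table, out = paths$tagged)
  dd <- dedup_bam(tg$sam, dedup_params(method = dedup_method, mode = mode),
                  out = paths$dedup)
  if (mode == "genome") {
    cnt <- count_genome(dd$sam, annotation)
  } else {
    cnt <- count_transcriptome(dd$sam,
                               tx2gene = if (!is.null(annotation)) annotation$tx2gene)
  }
  write_matrix(cnt$matrix, paths$matrix)
  metrics <- cell_metrics(cnt$matrix)

  msum <- mapping_summary(tg$sam)
  store <- stage_store()
  store <- record_stage(store, sample, "raw", ex$stats$n_input)
  store <- record_stage(store, sample, "trimmed",
                        ex$stats$n_input - ex$stats$n_filtered_out)
  store <- record_stage(store, sample, "structured", ex$stats$n_structured)
  store <- record_stage(store, sample, "aligned", msum$n_records)
  store <- record_stage(store, sample, "primary_mapped",
                        sum(flag_is_primary(tg$sam$records$flag) &
                              !flag_is_unmapped(tg$sam$records$flag)))
  store <- record_stage(store, sample, "cb_tagged", msum$n_cb_tagged)
  store <- record_stage(store, sample, "deduplicated", dd$stats$n_out)
  emit_tracking_csv(store, paths$tracking)
  check_funnel(store)

  list(whitelist = wl, corrected = corr, extract_stats = ex$stats,
       tag_stats = tg$stats, dedup_stats = dd$stats,
       matrix = cnt$matrix, count_stats = cnt$stats,
       metrics = metrics, tracking = store, paths = paths)
}
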