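# Gene- and transcript-level counting of deduplicated, CB-tagged alignments,
# and the MatrixMarket triplet layout used by single-cell tools. This is a
# deterministic overlap / reference-name counter so the pipeline is testable
# end-to-end at desk scale; model-based long-read quantifiers are out of
# scope by design.

#' Load a GTF annotation
#'
#' Parses exon features (via rtracklayer), unions exons per gene, and builds
#' the transcript maps used by splitting and transcript-level counting.
#' GTF 1-based inclusive intervals become 0-based half-open internally
#' (reported here as `GRanges`, which keep the 1-based convention of the
#' Bioconductor stack).
#'
#' @param gtf GTF path (exon features must carry `gene_id` and
#'   `transcript_id`).
#' @return list of class `annotation`: `genes` (named `GRangesList` of
#'   unioned exons per gene), `gene_meta` (data.frame `gene_id`, `gene_name`,
#'   `contig`, `strand`), `tx2chrom`, `tx2gene` (named character vectors).
#' @export
load_annotation <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop("GTF contains no exon features: ", gtf)
  if (is.null(ex$gene_id) || anyNA(ex$gene_id)) {
    bad <- if (is.null(ex$gene_id)) seq_along(ex) else which(is.na(ex$gene_id))
    stop("exon feature(s) without gene_id (e.g. exon #", bad[1], ") in ", gtf)
  }
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id)) {
    stop("exon feature(s) without transcript_id in ", gtf)
  }
  genes <- GenomicRanges::reduce(S4Vectors::split(ex, ex$gene_id))
  gene_ids <- names(genes)
  first <- match(gene_ids, ex$gene_id)
  gene_name <- if (!is.null(ex$gene_name)) ex$gene_name[first] else gene_ids
  gene_name[is.na(gene_name)] <- gene_ids[is.na(gene_name)]
  gene_meta <- data.frame(
    gene_id = gene_ids,
    gene_name = gene_name,
    contig = as.character(GenomicRanges::seqnames(ex))[first],
    strand = as.character(BiocGenerics::strand(ex))[first],
    stringsAsFactors = FALSE)
  tx_first <- !duplicated(ex$transcript_id)
  tx2chrom <- stats::setNames(as.character(GenomicRanges::seqnames(ex))[tx_first],
                              ex$transcript_id[tx_first])
  tx2gene <- stats::setNames(ex$gene_id[tx_first], ex$transcript_id[tx_first])
  structure(list(genes = genes, gene_meta = gene_meta,
                 tx2chrom = tx2chrom, tx2gene = tx2gene),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %d gene%s, %d transcript%s on %d contig%s\n",
              length(x$genes), if (length(x$genes) == 1) "" else "s",
              length(x$tx2gene), if (length(x$tx2gene) == 1) "" else "s",
              length(unique(x$tx2chrom)),
              if (length(unique(x$tx2chrom)) == 1) "" else "s"))
  invisible(x)
}

#' Assign an alignment to a gene by exonic overlap
#'
#' A gene is hit when its exon union covers at least `min_overlap` of the
#' alignment's aligned reference bases (CIGAR M/D/=/X, introns excluded).
#' Strand is ignored by default (ONT read strand is ambiguous relative to
#' the mRNA).
#'
#' @param rec single alignment record (row of a `sam_set`).
#' @param annotation an [load_annotation()] result.
#' @param min_overlap required fraction of aligned bases (default 0.5).
#' @return gene id, `"ambiguous"` (two or more genes reach the bar) or `NA`
#'   (none does, or the record is unmapped).
#' @export
assign_gene <- function(rec, annotation, min_overlap = 0.5) {
  assign_genes(structure(list(header = character(0),
                              records = as.data.frame(rec)),
                         class = "sam_set"),
               annotation, min_overlap)[1]
}

# Vectorised gene assignment for all mapped records of a sam_set.
assign_genes <- function(sam, annotation, min_overlap = 0.5) {
  rec <- sam$records
  n <- nrow(rec)
  out <- rep(NA_character_, n)
  mapped <- which(!flag_is_unmapped(rec$flag) & rec$rname != "*")
  if (length(mapped) == 0) return(out)
  blocks_list <- lapply(mapped, function(i) cigar_ref_blocks(rec$cigar[i], rec$pos[i]))
  nb <- vapply(blocks_list, length, integer(1))
  blocks <- GenomicRanges::GRanges(
    seqnames = rep(rec$rname[mapped], nb),
    ranges = do.call(c, blocks_list))
  aln_of_block <- rep(seq_along(mapped), nb)
  aligned_bases <- vapply(blocks_list, function(b) sum(IRanges::width(b)),
                          integer(1))
  exons <- unlist(annotation$genes)  # GRanges, names = gene ids (possibly dup)
  gene_of_exon <- names(exons)
  GenomeInfoDb::seqlevels(blocks) <-
    union(GenomeInfoDb::seqlevels(blocks), GenomeInfoDb::seqlevels(exons))
  GenomeInfoDb::seqlevels(exons) <- GenomeInfoDb::seqlevels(blocks)
  ov <- GenomicRanges::findOverlaps(blocks, exons, ignore.strand = TRUE)
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(blocks)[qh],
                                            IRanges::ranges(exons)[sh]))
    key <- paste(aln_of_block[qh], gene_of_exon[sh], sep = "\r")
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    aln_i <- as.integer(vapply(parts, `[`, character(1), 1))
    gene <- vapply(parts, `[`, character(1), 2)
    frac <- agg[, 1] / aligned_bases[aln_i]
    ok <- frac >= min_overlap
    if (any(ok)) {
      hits <- split(gene[ok], aln_i[ok])
      for (k in names(hits)) {
        i <- as.integer(k)
        out[mapped[i]] <- if (length(hits[[k]]) > 1) "ambiguous" else hits[[k]]
      }
    }
  }
  out
}

#' Construct a barcode-by-feature count matrix object
#'
#' @param counts data.frame with columns `barcode`, `feature_id`, `count`.
#' @param features data.frame `feature_id`, `feature_name`, `kind`
#'   (`"gene"`/`"transcript"`); features absent from `counts` are kept as
#'   all-zero rows.
#' @param barcodes optional barcode ordering (default: sorted barcodes seen
#'   in `counts`).
#' @return object of class `count_matrix`: sparse `features x barcodes`
#'   `dgCMatrix` in `$matrix` plus the `$features` table.
#' @export
count_matrix <- function(counts, features, barcodes = NULL) {
  if (is.null(barcodes)) barcodes <- sort(unique(counts$barcode))
  stopifnot(!anyDuplicated(features$feature_id), !anyDuplicated(barcodes))
  i <- match(counts$feature_id, features$feature_id)
  j <- match(counts$barcode, barcodes)
  if (anyNA(i)) stop("count for unknown feature: ",
                     counts$feature_id[which(is.na(i))[1]])
  if (anyNA(j)) stop("count for unknown barcode: ",
                     counts$barcode[which(is.na(j))[1]])
  m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(counts$count),
                            dims = c(nrow(features), length(barcodes)),
                            dimnames = list(features$feature_id, barcodes))
  structure(list(matrix = methods::as(m, "CsparseMatrix"), features = features),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d feature%s x %d barcode%s, %d non-zero, total mass %d\n",
              nrow(x$matrix), if (nrow(x$matrix) == 1) "" else "s",
              ncol(x$matrix), if (ncol(x$matrix) == 1) "" else "s",
              Matrix::nnzero(x$matrix), as.integer(sum(x$matrix))))
  invisible(x)
}

#' Gene-level counting of a deduplicated genome alignment file
#'
#' Each CB-tagged primary mapped record is assigned to a gene by
#' [assign_gene()]; ambiguous and unassigned records are excluded and
#' reported in `stats`. Matrix mass plus exclusions equals the number of
#' eligible records.
#'
#' @param bam_in deduplicated, tagged SAM/BAM path or `sam_set`.
#' @param annotation [load_annotation()] result (or GTF path).
#' @param min_overlap see [assign_gene()].
#' @return list with `matrix` (a `count_matrix`, kind `"gene"`) and `stats`
#'   (`n_records`, `n_assigned`, `n_ambiguous`, `n_unassigned`,
#'   `n_no_cb`).
#' @export
count_genome <- function(bam_in, annotation, min_overlap = 0.5) {
  sam <- if (is.character(bam_in)) read_sam(bam_in) else bam_in
  if (is.character(annotation)) annotation <- load_annotation(annotation)
  rec <- sam$records
  cb <- sam_get_tag(rec$tags, "CB")
  if (nrow(rec) > 0 && all(is.na(cb))) {
    stop("input carries no CB tags; tag and correct barcodes before counting")
  }
  eligible <- !is.na(cb) & flag_is_primary(rec$flag) & !flag_is_unmapped(rec$flag)
  gene <- rep(NA_character_, nrow(rec))
  gene[eligible] <- assign_genes(
    structure(list(header = sam$header,
                   records = rec[eligible, , drop = FALSE]), class = "sam_set"),
    annotation, min_overlap)
  ok <- eligible & !is.na(gene) & gene != "ambiguous"
  counts <- if (any(ok)) {
    agg <- table(cb[ok], gene[ok])
    df <- as.data.frame(agg, stringsAsFactors = FALSE)
    names(df) <- c("barcode", "feature_id", "count")
    df[df$count > 0, , drop = FALSE]
  } else data.frame(barcode = character(0), feature_id = character(0),
                    count = integer(0))
  meta <- annotation$gene_meta
  features <- data.frame(feature_id = meta$gene_id,
                         feature_name = meta$gene_name,
                         kind = "gene", stringsAsFactors = FALSE)
  list(matrix = count_matrix(counts, features),
       stats = list(n_records = nrow(rec),
                    n_assigned = sum(ok),
                    n_ambiguous = sum(gene == "ambiguous", na.rm = TRUE),
                    n_unassigned = sum(eligible & is.na(gene)),
                    n_no_cb = sum(!eligible)))
}

#' Transcript-level counting of a deduplicated transcriptome alignment file
#'
#' Counts CB-tagged primary records per (barcode, transcript reference).
#'
#' @param bam_in deduplicated, tagged SAM/BAM path or `sam_set` aligned to
#'   transcript references.
#' @param tx2gene named character vector transcript -> gene, used to resolve
#'   feature names (optional).
#' @param strict error on reference names absent from `tx2gene`.
#' @return list with `matrix` (a `count_matrix`, kind `"transcript"`) and
#'   `stats` (`n_records`, `n_counted`, `n_no_cb`).
#' @export
count_transcriptome <- function(bam_in, tx2gene = NULL, strict = FALSE) {
  sam <- if (is.character(bam_in)) read_sam(bam_in) else bam_in
  rec <- sam$records
  cb <- sam_get_tag(rec$tags, "CB")
  if (nrow(rec) > 0 && all(is.na(cb))) {
    stop("input carries no CB tags; tag and correct barcodes before counting")
  }
  ok <- !is.na(cb) & flag_is_primary(rec$flag) & !flag_is_unmapped(rec$flag)
  tx <- rec$rname[ok]
  if (strict && !is.null(tx2gene)) {
    bad <- unique(tx[!(tx %in% names(tx2gene))])
    if (length(bad)) stop("reference name(s) absent from tx2gene: ",
                          paste(utils::head(bad, 10), collapse = ", "))
  }
  counts <- if (any(ok)) {
    agg <- table(cb[ok], tx)
    df <- as.data.frame(agg, stringsAsFactors = FALSE)
    names(df) <- c("barcode", "feature_id", "count")
    df[df$count > 0, , drop = FALSE]
  } else data.frame(barcode = character(0), feature_id = character(0),
                    count = integer(0))
  tx_ids <- sort(unique(c(tx, names(tx2gene))))
  fname <- if (!is.null(tx2gene)) {
    g <- unname(tx2gene[tx_ids])
    ifelse(is.na(g), tx_ids, paste0(g, ":", tx_ids))
  } else tx_ids
  features <- data.frame(feature_id = tx_ids, feature_name = fname,
                         kind = "transcript", stringsAsFactors = FALSE)
  list(matrix = count_matrix(counts, features),
       stats = list(n_records = nrow(rec), n_counted = sum(ok),
                    n_no_cb = sum(!ok)))
}

#' Write a count matrix in the single-cell MatrixMarket layout
#'
#' Emits `matrix.mtx.gz` (coordinate format, features x barcodes, 1-based
#' indices, integer values), `barcodes.tsv.gz` and `features.tsv.gz`
#' (`feature_id`, `feature_name`, `kind`) into `out_dir`.
#'
#' @param cm a `count_matrix`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_matrix <- function(cm, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".mtx")
  Matrix::writeMM(cm$matrix, tmp)
  con <- gzfile(file.path(out_dir, "matrix.mtx.gz"), "w")
  writeLines(readLines(tmp), con)
  close(con)
  unlink(tmp)
  bc <- colnames(cm$matrix)
  con <- gzfile(file.path(out_dir, "barcodes.tsv.gz"), "w")
  writeLines(if (is.null(bc)) character(0) else bc, con)
  close(con)
  con <- gzfile(file.path(out_dir, "features.tsv.gz"), "w")
  writeLines(paste(cm$features$feature_id, cm$features$feature_name,
                   cm$features$kind, sep = "\t"), con)
  close(con)
  invisible(out_dir)
}

#' Read a count matrix written by [write_matrix()]
#'
#' @param dir directory containing `matrix.mtx(.gz)`, `barcodes.tsv(.gz)`,
#'   `features.tsv(.gz)`.
#' @return a `count_matrix`; `read_matrix(write_matrix(m)) == m`.
#' @export
read_matrix <- function(dir) {
  locate <- function(base) {
    for (p in file.path(dir, c(paste0(base, ".gz"), base))) {
      if (file.exists(p)) return(p)
    }
    stop("missing ", base, " in ", dir)
  }
  mtx_path <- locate("matrix.mtx")
  tmp <- tempfile(fileext = ".mtx")
  writeLines(readLines(mtx_path), tmp)  # readLines handles gz transparently
  m <- methods::as(Matrix::readMM(tmp), "CsparseMatrix")
  unlink(tmp)
  barcodes <- readLines(locate("barcodes.tsv"))
  feat <- utils::read.delim(locate("features.tsv"), header = FALSE,
                            stringsAsFactors = FALSE)
  names(feat) <- c("feature_id", "feature_name", "kind")[seq_len(ncol(feat))]
  dimnames(m) <- list(feat$feature_id, barcodes)
  structure(list(matrix = m, features = feat), class = "count_matrix")
}
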