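# Annotation loading, gene assignment, counting and matrix I/O.

toy_gtf <- function() {
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\tgene\t11\t100\t.\t+\t.\tgene_id "gA"; gene_name "GeneA";',
    'chr1\ttoy\ttranscript\t11\t100\t.\t+\t.\tgene_id "gA"; transcript_id "tA1"; gene_name "GeneA";',
    'chr1\ttoy\texon\t11\t20\t.\t+\t.\tgene_id "gA"; transcript_id "tA1"; gene_name "GeneA";',
    'chr1\ttoy\texon\t41\t100\t.\t+\t.\tgene_id "gA"; transcript_id "tA1"; gene_name "GeneA";',
    'chr1\ttoy\ttranscript\t15\t100\t.\t+\t.\tgene_id "gA"; transcript_id "tA2"; gene_name "GeneA";',
    'chr1\ttoy\texon\t15\t45\t.\t+\t.\tgene_id "gA"; transcript_id "tA2"; gene_name "GeneA";',
    'chr2\ttoy\tgene\t201\t400\t.\t-\t.\tgene_id "gB"; gene_name "GeneB";',
    'chr2\ttoy\ttranscript\t201\t400\t.\t-\t.\tgene_id "gB"; transcript_id "tB1"; gene_name "GeneB";',
    'chr2\ttoy\texon\t201\t400\t.\t-\t.\tgene_id "gB"; transcript_id "tB1"; gene_name "GeneB";'),
    p)
  p
}

test_that("load_annotation builds gene models, unions exons and maps", {
  ann <- load_annotation(toy_gtf())
  expect_length(ann$genes, 2L)
  expect_length(ann$tx2gene, 3L)
  expect_equal(unname(ann$tx2gene[c("tA1", "tA2", "tB1")]),
               c("gA", "gA", "gB"))
  expect_equal(unname(ann$tx2chrom[c("tA1", "tB1")]), c("chr1", "chr2"))
  # overlapping exons union: [11,20] + [15,45] + [41,100] -> [11,100]
  gA <- ann$genes[["gA"]]
  expect_equal(length(gA), 1L)
  expect_equal(BiocGenerics::start(gA), 11L)
  expect_equal(BiocGenerics::end(gA), 100L)
  # GTF 1-based inclusive [11,20] has width 10
  single <- load_annotation({
    p <- tempfile(fileext = ".gtf")
    writeLines('chr1\ttoy\texon\t11\t20\t.\t+\t.\tgene_id "g"; transcript_id "t";', p)
    p
  })
  expect_equal(IRanges::width(single$genes[["g"]]), 10L)
})

test_that("load_annotation rejects GTFs without usable exons", {
  p <- tempfile(fileext = ".gtf")
  writeLines('chr1\ttoy\tgene\t1\t10\t.\t+\t.\tgene_id "g";', p)
  expect_error(load_annotation(p), "no exon")
})

test_that("assign_gene uses the 50% aligned-base overlap bar", {
  ann <- load_annotation(toy_gtf())
  inside <- make_sam(list(list(qname = "in", pos = 50L, cigar = "20M",
                               seq = strrep("A", 20), qual = strrep("I", 20))))
  expect_equal(assign_gene(inside$records[1, ], ann), "gA")
  intergenic <- make_sam(list(list(qname = "out", pos = 5000L, cigar = "20M",
                                   seq = strrep("A", 20), qual = strrep("I", 20))))
  expect_true(is.na(assign_gene(intergenic$records[1, ], ann)))
  # two overlapping genes both covering the read: ambiguous
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\texon\t100\t200\t.\t-\t.\tgene_id "g2"; transcript_id "t2";'), p)
  ann2 <- load_annotation(p)
  r <- make_sam(list(list(qname = "amb", pos = 120L, cigar = "50M",
                          seq = strrep("A", 50), qual = strrep("I", 50))))
  expect_equal(assign_gene(r$records[1, ], ann2), "ambiguous")
  # a spliced alignment is judged on its aligned bases only
  spliced <- make_sam(list(list(qname = "sp", pos = 11L, cigar = "10M20N30M",
                                seq = strrep("A", 40), qual = strrep("I", 40))))
  expect_equal(assign_gene(spliced$records[1, ], ann), "gA")
})

test_that("count_genome aggregates per cell and conserves mass", {
  ann <- load_annotation(toy_gtf())
  mk <- function(qname, cb, rname, pos) {
    list(qname = qname, rname = rname, pos = pos, cigar = "20M",
         seq = strrep("A", 20), qual = strrep("I", 20),
         tags = paste0("CB:Z:", cb, "\tUR:Z:AAAA"))
  }
  sam <- make_sam(list(mk("r1", "c1", "chr1", 50L), mk("r2", "c1", "chr1", 60L),
                       mk("r3", "c1", "chr1", 70L), mk("r4", "c2", "chr2", 250L),
                       mk("r5", "c2", "chr2", 300L)))
  out <- count_genome(sam, ann)
  m <- out$matrix$matrix
  expect_equal(sum(m), 5)
  expect_equal(as.numeric(m["gA", "c1"]), 3)
  expect_equal(as.numeric(m["gB", "c2"]), 2)
  expect_equal(out$stats$n_assigned + out$stats$n_ambiguous +
                 out$stats$n_unassigned + out$stats$n_no_cb,
               out$stats$n_records)
  expect_error(count_genome(make_sam(list(list(qname = "r"))), ann), "CB")
})

test_that("zero-error simulation reproduces the truth matrix exactly", {
  sim <- get_sim("clean10", n_cells = 10L, reads_per_cell = 20L)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(sim$reference$gtf, gtf)
  ann <- load_annotation(gtf)
  sam <- simulate_alignments(sim, "genome")
  tab <- data.frame(read_id = sim$truth$read_id,
                    barcode = sim$truth$cell_barcode,
                    barcode_quals = q_string(30, 16),
                    umi = sim$truth$umi, umi_quals = q_string(30, 12),
                    strand = sim$truth$strand,
                    corrected_barcode = sim$truth$cell_barcode,
                    posterior = 1, status = "exact", stringsAsFactors = FALSE)
  dd <- dedup_bam(tag_bam(sam, tab)$sam, dedup_params(mode = "genome"))
  out <- count_genome(dd$sam, ann)
  got <- as.matrix(out$matrix$matrix)
  want <- as.matrix(sim$truth_matrix$matrix)
  expect_identical(got[rownames(want), colnames(want)], want)
})

test_that("count_transcriptome counts primaries per reference", {
  mk <- function(qname, cb, rname, flag = 0L) {
    list(qname = qname, flag = flag, rname = rname, pos = 1L, cigar = "20M",
         seq = strrep("A", 20), qual = strrep("I", 20),
         tags = paste0("CB:Z:", cb, "\tUR:Z:AAAA"))
  }
  sam <- make_sam(list(mk("r1", "c1", "t1"), mk("r2", "c1", "t1"),
                       mk("r3", "c1", "t2"),
                       mk("r3", "c1", "t1", flag = 256L)),  # secondary: ignored
                  contigs = c(t1 = 1000L, t2 = 1000L))
  out <- count_transcriptome(sam, tx2gene = c(t1 = "gA", t2 = "gB"))
  m <- out$matrix$matrix
  expect_equal(as.numeric(m["t1", "c1"]), 2)
  expect_equal(as.numeric(m["t2", "c1"]), 1)
  expect_equal(sum(m), out$stats$n_counted)
  expect_equal(out$matrix$features$feature_name[
    out$matrix$features$feature_id == "t1"], "gA:t1")
  expect_error(count_transcriptome(sam, tx2gene = c(t1 = "gA"), strict = TRUE),
               "t2")
})

test_that("matrices round-trip through the MatrixMarket layout", {
  counts <- data.frame(barcode = c("c1", "c2", "c1"),
                       feature_id = c("g1", "g2", "g2"),
                       count = c(3L, 2L, 1L), stringsAsFactors = FALSE)
  features <- data.frame(feature_id = c("g1", "g2", "g3"),
                         feature_name = c("A", "B", "C"), kind = "gene",
                         stringsAsFactors = FALSE)
  cm <- count_matrix(counts, features)
  d <- tempfile()
  write_matrix(cm, d)
  expect_true(all(file.exists(file.path(d, c("matrix.mtx.gz", "barcodes.tsv.gz",
                                             "features.tsv.gz")))))
  back <- read_matrix(d)
  expect_equal(as.matrix(back$matrix), as.matrix(cm$matrix))
  expect_equal(back$features, cm$features)
  # the coordinate header declares one entry per non-zero triplet
  lines <- readLines(file.path(d, "matrix.mtx.gz"))
  hdr <- as.integer(strsplit(lines[!startsWith(lines, "%")][1], " ")[[1]])
  expect_equal(hdr, c(3L, 2L, 3L))  # features x barcodes x nnz
  expect_equal(sum(cm$matrix), 6)
  # empty matrix stays valid
  cm0 <- count_matrix(counts[0, ], features)
  d0 <- tempfile()
  write_matrix(cm0, d0)
  back0 <- read_matrix(d0)
  expect_equal(Matrix::nnzero(back0$matrix), 0L)
  expect_equal(dim(back0$matrix), c(3L, 0L))
})
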