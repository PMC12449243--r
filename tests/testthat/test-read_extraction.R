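# Read filtering and 10X structure parsing.

test_that("filter_reads enforces length and quality bounds", {
  reads <- data.frame(
    read_id = c("short", "lowq", "ok"),
    sequence = c(strrep("A", 50), strrep("A", 150), strrep("A", 150)),
    qualities = c(q_string(30, 50), q_string(5, 150), q_string(30, 150)),
    stringsAsFactors = FALSE)
  out <- filter_reads(reads, min_mean_quality = 10, min_length = 100,
                      max_length = 1000)
  expect_equal(out$kept$read_id, "ok")
  expect_equal(out$n_dropped, 2L)
  # all-Q30 read passes a Q10 bar regardless of content
  out2 <- filter_reads(reads[3, ], min_mean_quality = 10)
  expect_equal(out2$n_dropped, 0L)
})

test_that("filter_reads recovers a constructed 60/40 split", {
  set.seed(101)
  good <- lapply(1:60, function(i) data.frame(
    read_id = paste0("g", i), sequence = rand_kmer(150),
    qualities = q_string(30, 150), stringsAsFactors = FALSE))
  short <- lapply(1:15, function(i) data.frame(
    read_id = paste0("s", i), sequence = rand_kmer(50),
    qualities = q_string(30, 50), stringsAsFactors = FALSE))
  long <- lapply(1:10, function(i) data.frame(
    read_id = paste0("l", i), sequence = rand_kmer(900),
    qualities = q_string(30, 900), stringsAsFactors = FALSE))
  lowq <- lapply(1:15, function(i) data.frame(
    read_id = paste0("q", i), sequence = rand_kmer(150),
    qualities = q_string(4, 150), stringsAsFactors = FALSE))
  reads <- do.call(rbind, c(good, short, long, lowq))
  out <- filter_reads(reads, min_mean_quality = 10, min_length = 100,
                      max_length = 500)
  expect_equal(nrow(out$kept), 60L)
  expect_equal(out$n_dropped, 40L)
  expect_equal(nrow(out$kept) + out$n_dropped, nrow(reads))
  # order preserved
  expect_equal(out$kept$read_id, paste0("g", 1:60))
})

test_that("filter_reads rejects malformed read tables naming the read", {
  bad <- data.frame(read_id = "broken", sequence = "ACGT", qualities = "III",
                    stringsAsFactors = FALSE)
  expect_error(filter_reads(bad), "broken")
})

chem <- toy_chem()
bc <- "ACGTACGT"; umi <- "AACCGG"
polyt <- "TTTTTTGTTTTT"  # 12 nt run with one tolerated non-T
cdna <- "GACCTGATTGACCATGGCACAGTTCCTAAGGACCAAGGTCAGGAGACCAA"
fixture <- data.frame(
  read_id = "fix1",
  sequence = paste0(chem$adapter, bc, umi, polyt, cdna),
  qualities = q_string(30, nchar(chem$adapter) + 8 + 6 + 12 + nchar(cdna)),
  stringsAsFactors = FALSE)

test_that("locate_structure finds a constructed error-free layout", {
  hit <- locate_structure(fixture, chem)
  expect_s3_class(hit, "structure_hit")
  expect_equal(hit$strand, "+")
  expect_equal(hit$adapter_dist, 0L)
  expect_equal(hit$adapter_end, nchar(chem$adapter))
  expect_equal(c(hit$bc_start, hit$bc_end),
               nchar(chem$adapter) + c(0L, 8L))
  expect_equal(c(hit$umi_start, hit$umi_end),
               nchar(chem$adapter) + 8L + c(0L, 6L))
  expect_equal(hit$polyt_end, hit$umi_end + nchar(polyt))
})

test_that("the reverse complement recovers the same barcode and UMI on '-'", {
  rc <- data.frame(read_id = "fix1rc",
                   sequence = revcomp(fixture$sequence),
                   qualities = fixture$qualities,  # symmetric qualities
                   stringsAsFactors = FALSE)
  hit_f <- locate_structure(fixture, chem)
  hit_r <- locate_structure(rc, chem)
  expect_equal(hit_r$strand, "-")
  ex_f <- extract_read(fixture, hit_f, chem)
  ex_r <- extract_read(rc, hit_r, chem)
  expect_equal(ex_r$record$barcode, ex_f$record$barcode)
  expect_equal(ex_r$record$umi, ex_f$record$umi)
  expect_equal(ex_r$trimmed$sequence, ex_f$trimmed$sequence)
})

test_that("a random read with no adapter yields no structure", {
  set.seed(7)
  rnd <- data.frame(read_id = "noise", sequence = rand_kmer(200),
                    qualities = q_string(30, 200), stringsAsFactors = FALSE)
  expect_null(locate_structure(rnd, get_chemistry("10x-3p-v3")))
})

test_that("extract_read trims through the poly-T and conserves lengths", {
  hit <- locate_structure(fixture, chem)
  ex <- extract_read(fixture, hit, chem)
  expect_equal(ex$trimmed$sequence, cdna)
  expect_equal(nchar(ex$trimmed$sequence), nchar(ex$trimmed$qualities))
  expect_equal(nchar(ex$trimmed$sequence),
               nchar(fixture$sequence) -
                 (nchar(chem$adapter) + 8L + 6L + nchar(polyt)))
  expect_equal(ex$record$barcode, bc)
  expect_equal(ex$record$umi, umi)
  # without a poly-T hit, trimming starts right after the UMI
  hit$polyt_end <- NA_integer_
  ex2 <- extract_read(fixture, hit, chem)
  expect_equal(ex2$trimmed$sequence, paste0(polyt, cdna))
})

test_that("extract_read rejects out-of-bounds spans", {
  hit <- locate_structure(fixture, chem)
  hit$umi_end <- nchar(fixture$sequence) + 50L
  hit$polyt_end <- NA_integer_
  expect_error(extract_read(fixture, hit, chem), "outside")
})

test_that("extract_batch on error-free simulated reads recovers everything", {
  sim <- get_sim("clean10", n_cells = 10L, reads_per_cell = 20L)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  put <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(read_id = sim$truth$read_id,
                              putative_bc = sim$truth$cell_barcode,
                              putative_bc_min_q = 30),
                   put, row.names = FALSE)
  out <- extract_batch(fq, sim$params$chemistry,
                       tempfile(fileext = ".fastq"),
                       tempfile(fileext = ".csv"),
                       putative_table = put)
  expect_equal(out$stats$n_structured, nrow(sim$reads))
  expect_equal(out$stats$n_unstructured, 0L)
  expect_equal(out$stats$n_discordant, 0L)
  tab <- read_barcode_table(out$table_out)
  m <- match(tab$read_id, sim$truth$read_id)
  # zero-error recovery: barcode, UMI and strand all equal the truth table
  expect_true(all(tab$barcode == sim$truth$cell_barcode[m]))
  expect_true(all(tab$umi == sim$truth$umi[m]))
  expect_true(all(tab$strand == sim$truth$strand[m]))
  # lockstep trimming in the emitted FASTQ
  trimmed <- read_fastq(out$fastq_out)
  expect_true(all(nchar(trimmed$sequence) == nchar(trimmed$qualities)))
})

test_that("an empty FASTQ produces empty outputs and zero stats", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  out <- extract_batch(fq, toy_chem(), tempfile(fileext = ".fastq"),
                       tempfile(fileext = ".csv"))
  expect_equal(out$stats$n_input, 0L)
  expect_equal(out$stats$n_structured, 0L)
  expect_equal(nrow(read_barcode_table(out$table_out)), 0L)
  expect_equal(nrow(read_fastq(out$fastq_out)), 0L)
})

test_that("structure conservation holds at a 2% substitution rate", {
  sim <- get_sim("noisy10", n_cells = 10L, reads_per_cell = 20L,
                 sub_rate = 0.02)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  out <- extract_batch(fq, sim$params$chemistry,
                       tempfile(fileext = ".fastq"),
                       tempfile(fileext = ".csv"))
  s <- out$stats
  expect_equal(s$n_structured + s$n_unstructured, s$n_input)
  expect_gte(s$n_structured / s$n_input, 0.95)
})

test_that("strict putative-table mode reports missing read ids", {
  sim <- get_sim("clean10", n_cells = 10L, reads_per_cell = 20L)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads[1:5, ], fq)
  put <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(read_id = "absent", putative_bc = "AAAA"),
                   put, row.names = FALSE)
  expect_error(
    extract_batch(fq, sim$params$chemistry, tempfile(fileext = ".fastq"),
                  tempfile(fileext = ".csv"), putative_table = put,
                  strict = TRUE),
    "read00")
})
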