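# Whitelist construction and posterior barcode correction.

test_that("hamming_distance counts mismatching positions", {
  expect_equal(hamming_distance("ACGT", "ACGT"), 0L)
  expect_equal(hamming_distance("ACGT", "ACGA"), 1L)
  expect_equal(hamming_distance("AAAA", "TTTT"), 4L)
  expect_error(hamming_distance("AAA", "AAAA"), "unequal")
})

test_that("rank_barcodes orders by count then barcode, gated on quality", {
  recs <- data.frame(
    read_id = paste0("r", 1:8),
    barcode = c(rep("CCCC", 5), rep("AAAA", 3)),
    barcode_quals = q_string(30, 4),
    umi = "AAAAAA", umi_quals = q_string(30, 6), strand = "+",
    stringsAsFactors = FALSE)
  rk <- rank_barcodes(recs, 15)
  expect_equal(rk$barcode, c("CCCC", "AAAA"))
  expect_equal(rk$count, c(5L, 3L))
  expect_equal(rk$rank, 1:2)
  # tie on counts: lexicographically smaller barcode ranks first
  recs2 <- recs[c(1, 2, 6, 7), ]
  rk2 <- rank_barcodes(recs2, 15)
  expect_equal(rk2$barcode[1], "AAAA")
  # all below the quality gate: empty
  recs$barcode_quals <- q_string(5, 4)
  expect_equal(nrow(rank_barcodes(recs, 15)), 0L)
})

test_that("build_whitelist applies the expected-cells quantile rule", {
  ranked <- data.frame(barcode = sprintf("BC%02d", 1:6),
                       count = c(100L, 90L, 80L, 5L, 4L, 3L), rank = 1:6,
                       stringsAsFactors = FALSE)
  wl <- build_whitelist(ranked, expected_cells = 3)
  # anchor rank = ceiling(0.05 * 3) = 1 -> threshold = 100 / 20 = 5
  expect_equal(wl$barcode, ranked$barcode[1:3])
  single <- ranked[1, ]
  expect_equal(nrow(build_whitelist(single, expected_cells = 1)), 1L)
  expect_error(build_whitelist(ranked, expected_cells = 10), "exceeds")
})

test_that("knee whitelist recovers simulated true cells", {
  sim <- get_sim("noisy25", n_cells = 25L, reads_per_cell = 40L,
                 sub_rate = 0.02, seed = 5L)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  out <- extract_batch(fq, sim$params$chemistry,
                       tempfile(fileext = ".fastq"), tempfile(fileext = ".csv"))
  ranked <- rank_barcodes(read_barcode_table(out$table_out), 15)
  wl <- build_whitelist(ranked, expected_cells = NULL)
  recall <- sum(sim$whitelist$barcode %in% wl$barcode) / nrow(sim$whitelist)
  expect_gte(recall, 0.95)
})

test_that("candidates_within matches the linear-scan oracle", {
  wl <- data.frame(barcode = c("AAAA", "AAAT", "GGGG"), count = c(3L, 2L, 1L),
                   rank = 1:3, stringsAsFactors = FALSE)
  got <- candidates_within("AAAC", wl, 1L)
  expect_setequal(got$barcode, c("AAAA", "AAAT"))
  expect_equal(candidates_within("GGGG", wl, 0L)$barcode, "GGGG")
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    wl <- data.frame(barcode = unique(replicate(n, rand_kmer(8))),
                     stringsAsFactors = FALSE)
    wl$count <- seq_len(nrow(wl)); wl$rank <- seq_len(nrow(wl))
    q <- if (runif(1) < 0.5) rand_kmer(8) else {
      b <- strsplit(sample(wl$barcode, 1), "")[[1]]
      i <- sample(8, 1); b[i] <- sample(c("A", "C", "G", "T"), 1)
      paste(b, collapse = "")
    }
    d <- sample(0:3, 1)
    expect_setequal(candidates_within(q, wl, d)$barcode,
                    oracle_candidates(q, wl, d))
  }
})

test_that("posterior follows the quality-weighted abundance model", {
  params <- correction_params()
  # single candidate -> certainty
  wl1 <- data.frame(barcode = "AAAA", count = 1L, rank = 1L,
                    stringsAsFactors = FALSE)
  p1 <- barcode_posterior("AAAT", q_string(10, 4), candidates_within("AAAT", wl1, 2), params)
  expect_equal(p1, 1.0)
  # symmetric case: equal priors and equal single-mismatch likelihoods
  wl2 <- data.frame(barcode = c("AAAA", "AAAT"), count = c(1L, 1L),
                    rank = 1:2, stringsAsFactors = FALSE)
  p2 <- barcode_posterior("AAAG", q_string(10, 4),
                          candidates_within("AAAG", wl2, 2), params)
  expect_equal(p2, c(0.5, 0.5), tolerance = 1e-12)
  # 9:1 abundance prior with zero pseudocount
  wl3 <- data.frame(barcode = c("AAAA", "AAAT"), count = c(9L, 1L),
                    rank = 1:2, stringsAsFactors = FALSE)
  p3 <- barcode_posterior("AAAG", q_string(10, 4),
                          candidates_within("AAAG", wl3, 2),
                          correction_params(prior_pseudocount = 0))
  expect_equal(p3, c(0.9, 0.1), tolerance = 1e-12)
})

test_that("posteriors normalise to one over random candidate sets", {
  set.seed(23)
  for (rep in 1:50) {
    wl <- data.frame(barcode = unique(replicate(30, rand_kmer(6))),
                     stringsAsFactors = FALSE)
    wl$count <- sample(1:50, nrow(wl), replace = TRUE)
    wl$rank <- seq_len(nrow(wl))
    q <- rand_kmer(6)
    cand <- candidates_within(q, wl, 3L)
    if (nrow(cand) == 0) next
    post <- barcode_posterior(q, phred_encode(sample(5:40, 6, TRUE)), cand)
    expect_equal(sum(post), 1, tolerance = 1e-9)
  }
})

test_that("correct_barcode statuses follow the threshold contract", {
  wl <- data.frame(barcode = c("AAAA", "AAAT"), count = c(1L, 1L),
                   rank = 1:2, stringsAsFactors = FALSE)
  # exact: sole candidate, posterior 1
  r <- correct_barcode("GGGG",
                       q_string(30, 4),
                       data.frame(barcode = "GGGG", count = 5L, rank = 1L,
                                  stringsAsFactors = FALSE))
  expect_equal(r$status, "exact")
  expect_equal(r$posterior, 1.0)
  # the symmetric (0.5, 0.5) case is ambiguous at 0.975
  r2 <- correct_barcode("AAAG", q_string(10, 4), wl)
  expect_equal(r2$status, "ambiguous")
  expect_true(is.na(r2$corrected_barcode))
  expect_equal(r2$n_candidates, 2L)
  # beyond max_hamming from everything: no candidate
  r3 <- correct_barcode("CCCC", q_string(30, 4), wl)
  expect_equal(r3$status, "no_candidate")
  expect_equal(r3$n_candidates, 0L)
  # clear winner gets corrected
  wl4 <- data.frame(barcode = "AAAA", count = 10L, rank = 1L,
                    stringsAsFactors = FALSE)
  r4 <- correct_barcode("AAAT", q_string(30, 4), wl4)
  expect_equal(r4$status, "corrected")
  expect_equal(r4$corrected_barcode, "AAAA")
})

test_that("whitelist barcodes at high quality are idempotent under correction", {
  set.seed(31)
  wl <- data.frame(barcode = unique(replicate(40, rand_kmer(8))),
                   stringsAsFactors = FALSE)
  wl$count <- sample(5:100, nrow(wl), replace = TRUE)
  wl$rank <- rank(-wl$count, ties.method = "first")
  for (b in sample(wl$barcode, 10)) {
    r <- correct_barcode(b, q_string(30, 8), wl)
    expect_equal(r$status, "exact")
    expect_equal(r$corrected_barcode, b)
  }
})

test_that("raising the posterior threshold never accepts more barcodes", {
  sim <- get_sim("noisy10", n_cells = 10L, reads_per_cell = 20L,
                 sub_rate = 0.02)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  out <- extract_batch(fq, sim$params$chemistry,
                       tempfile(fileext = ".fastq"), tempfile(fileext = ".csv"))
  tab <- read_barcode_table(out$table_out)
  accepted <- vapply(c(0.5, 0.9, 0.975, 0.999), function(thr) {
    st <- correct_table(tab, sim$whitelist,
                        correction_params(posterior_threshold = thr))$stats
    st$exact + st$corrected
  }, numeric(1))
  expect_true(all(diff(accepted) <= 0))
})

test_that("correct_table handles empty input and schema violations", {
  empty <- correct_table(
    data.frame(read_id = character(0), barcode = character(0),
               barcode_quals = character(0), stringsAsFactors = FALSE),
    data.frame(barcode = "AAAA", count = 1L, rank = 1L,
               stringsAsFactors = FALSE))
  expect_equal(nrow(empty$table), 0L)
  expect_equal(empty$stats$n_rows, 0L)
  expect_error(
    correct_table(data.frame(read_id = "x", stringsAsFactors = FALSE),
                  data.frame(barcode = "AAAA", count = 1L, rank = 1L)),
    "missing column")
})

test_that("whitelist files round-trip with and without counts", {
  wl <- data.frame(barcode = c("ACGTACGT", "TTTTCCCC"), count = c(10L, 3L),
                   rank = 1:2, stringsAsFactors = FALSE)
  p <- tempfile()
  write_whitelist(wl, p)
  back <- read_whitelist(p)
  expect_equal(back$barcode, wl$barcode)
  expect_equal(back$count, wl$count)
  writeLines(c("AAAA", "CCCC"), p)
  bare <- read_whitelist(p)
  expect_equal(bare$count, c(0L, 0L))
})
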