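# Independent oracles and small fixture builders shared across tests.

# Toy chemistry with a short adapter so fixtures stay readable.
toy_chem <- function() {
  chemistry_profile("toy", adapter = "CTACACGACG", barcode_length = 8L,
                    umi_length = 6L, polyt_min_run = 6L,
                    max_adapter_edit_distance = 2L, search_window = 40L)
}

rand_kmer <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                               collapse = "")

q_string <- function(q, n) paste(rep(rawToChar(as.raw(q + 33L)), n), collapse = "")

# Exhaustive linear-scan candidate search (independent of the package path).
oracle_candidates <- function(query, whitelist, d) {
  keep <- vapply(whitelist$barcode, function(b) {
    sum(strsplit(query, "")[[1]] != strsplit(b, "")[[1]]) <= d
  }, logical(1))
  whitelist$barcode[keep]
}

# Brute-force directional clustering: repeatedly seed at the highest-count
# unclaimed UMI and take everything reachable in the unclaimed subgraph,
# computed by boolean transitive closure (matrix powers) — a different
# construction from the package's BFS.
oracle_directional <- function(counts, d = 1L) {
  umis <- names(sort(counts))             # stable base order
  counts <- counts[umis]
  ord <- order(-as.integer(counts), umis)
  umis <- umis[ord]; cnt <- as.integer(counts[ord])
  n <- length(umis)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && ham(umis[i], umis[j]) <= d && cnt[i] >= 2L * cnt[j] - 1L) {
      A[i, j] <- TRUE
    }
  }
  unclaimed <- rep(TRUE, n)
  clusters <- list()
  while (any(unclaimed)) {
    seed <- which(unclaimed)[1]           # highest count (then lex) unclaimed
    sub <- which(unclaimed)
    As <- A[sub, sub, drop = FALSE]
    reach <- diag(TRUE, length(sub))
    repeat {
      nxt <- reach | (reach %*% As > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    members <- sub[reach[match(seed, sub), ]]
    unclaimed[members] <- FALSE
    # members come out in count-descending / lexicographic order, so the
    # first one is the representative under the stated tie-break
    clusters[[length(clusters) + 1L]] <-
      list(representative = umis[members[1]], members = sort(umis[members]))
  }
  clusters
}

# Canonical form for comparing clusterings: sorted member sets + reps.
cluster_sets <- function(clusters, member_field = "member_umis") {
  sets <- lapply(clusters, function(cl) {
    if (!is.null(cl$members)) sort(cl$members) else sort(names(cl[[member_field]]))
  })
  sets[order(vapply(sets, `[`, character(1), 1))]
}

# Minimal sam_set builder for hand fixtures.
make_sam <- function(records, contigs = c(chr1 = 10000L, chr2 = 10000L)) {
  defaults <- data.frame(qname = "r", flag = 0L, rname = "chr1", pos = 1L,
                         mapq = 60L, cigar = "10M", rnext = "*", pnext = 0L,
                         tlen = 0L, seq = strrep("A", 10), qual = strrep("I", 10),
                         tags = "", stringsAsFactors = FALSE)
  rec <- do.call(rbind, lapply(records, function(r) {
    row <- defaults
    for (nm in names(r)) row[[nm]] <- r[[nm]]
    row
  }))
  structure(list(header = c("@HD\tVN:1.6\tSO:coordinate",
                            sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                                    unname(contigs))),
                 records = rec),
            class = "sam_set")
}

# Small shared simulations (built once per test run).
sim_cache <- new.env(parent = emptyenv())
get_sim <- function(name, n_cells, reads_per_cell, sub_rate = 0, seed = 42L,
                    n_genes = 6L) {
  if (!is.null(sim_cache[[name]])) return(sim_cache[[name]])
  ref <- make_toy_reference(n_genes, 2L, seed = seed)
  sim <- simulate_reads(sim_params(n_cells = n_cells, n_genes = n_genes,
                                   reads_per_cell = reads_per_cell,
                                   sub_rate = sub_rate, seed = seed), ref)
  sim_cache[[name]] <- sim
  sim
}
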