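# Deterministic synthetic-data generator: toy two-contig reference, ONT-like
# single-cell reads with known barcodes/UMIs/errors, truth tables, and
# perfect-placement SAM. The error model is independent per-base
# substitution/insertion/deletion (no homopolymer bias) — enough to exercise
# the Hamming/posterior logic. Substituted and inserted bases are reported
# with low basecall qualities (Q 3-12) and correct bases with Q 20-40,
# mirroring the quality/error correlation of real ONT basecalls that the
# whitelist quality gate and posterior model rely on.

GOOD_Q <- 20:40
ERROR_Q <- 3:12
BASES <- c("A", "C", "G", "T")

#' Simulation parameters
#'
#' @param n_cells number of real cells (default 50).
#' @param n_genes,isoforms_per_gene toy reference size (defaults 8 and 2).
#' @param reads_per_cell reads emitted per cell (default 40).
#' @param umi_length UMI length in nt (default 12, 3' v3 chemistry).
#' @param sub_rate,ins_rate,del_rate independent per-base error
#'   probabilities, each in `[0, 0.5)`.
#' @param dup_rate PCR-duplication level: each cell's molecule pool has
#'   `round(reads_per_cell * (1 - dup_rate))` molecules which reads sample
#'   with replacement (default 0.2).
#' @param chemistry a [chemistry_profile()] (default `10x-3p-v3`).
#' @param seed integer; fixes all randomness (byte-identical outputs).
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_cells = 50L, n_genes = 8L, isoforms_per_gene = 2L,
                       reads_per_cell = 40L, umi_length = 12L,
                       sub_rate = 0, ins_rate = 0, del_rate = 0,
                       dup_rate = 0.2, chemistry = get_chemistry("10x-3p-v3"),
                       seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  stopifnot(all(rates >= 0), all(rates < 0.5),
            n_cells > 0, n_genes > 0, isoforms_per_gene > 0,
            reads_per_cell > 0, umi_length > 0,
            dup_rate >= 0, dup_rate < 1)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 reads_per_cell = as.integer(reads_per_cell),
                 umi_length = as.integer(umi_length),
                 sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 dup_rate = dup_rate, chemistry = chemistry,
                 seed = as.integer(seed)),
            class = "sim_params")
}

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Build a toy reference: genome, annotation, transcripts
#'
#' Genes are placed without overlap, alternating over two contigs and both
#' strands; each gene has `isoforms_per_gene + 1` exons (minimum 3) and each
#' isoform beyond the first drops one distinct internal exon. Transcript
#' sequences are the exon concatenation from the genome (reverse-complemented
#' on the minus strand).
#'
#' @param n_genes,isoforms_per_gene reference size.
#' @param seed RNG seed; the same seed gives byte-identical outputs.
#' @param out_dir optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf` and `transcripts.fa`.
#' @return list of class `toy_reference`: `genome` (named character),
#'   `transcripts` (named character), `gtf` (character lines), `tx2chrom`,
#'   `tx2gene`, `tx_exons` (per-transcript data.frame of exon blocks:
#'   `t_off`, `len`, `g_start0`, `strand`, `contig`), `gene_meta`, and file
#'   `paths` when written.
#' @export
make_toy_reference <- function(n_genes = 8L, isoforms_per_gene = 2L,
                               seed = 1L, out_dir = NULL) {
  stopifnot(n_genes > 0, isoforms_per_gene > 0)
  with_seed(seed, {
    contigs <- c("chr1", "chr2")
    offsets <- stats::setNames(rep(200L, 2), contigs)
    n_exons <- max(3L, isoforms_per_gene + 1L)
    gtf <- character(0)
    tx2chrom <- character(0); tx2gene <- character(0)
    tx_exons <- list(); tx_seq_plan <- list()
    gene_meta <- data.frame(gene_id = character(0), gene_name = character(0),
                            contig = character(0), strand = character(0),
                            stringsAsFactors = FALSE)
    for (g in seq_len(n_genes)) {
      gid <- sprintf("G%02d", g)
      contig <- contigs[(g - 1L) %% 2L + 1L]
      strand <- if (g %% 2L == 1L) "+" else "-"
      ex_len <- sample(120:250, n_exons, replace = TRUE)
      in_len <- sample(60:150, n_exons - 1L, replace = TRUE)
      start0 <- offsets[[contig]]
      ex_start0 <- start0 + cumsum(c(0L, ex_len[-n_exons] + in_len))
      ex_end0 <- ex_start0 + ex_len  # half-open
      offsets[[contig]] <- ex_end0[n_exons] + 300L
      gene_meta <- rbind(gene_meta, data.frame(
        gene_id = gid, gene_name = gid, contig = contig, strand = strand,
        stringsAsFactors = FALSE))
      gtf <- c(gtf, sprintf(
        "%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
        contig, ex_start0[1] + 1L, ex_end0[n_exons], strand, gid, gid))
      for (k in seq_len(isoforms_per_gene)) {
        tid <- sprintf("%s.%d", gid, k)
        use <- if (k == 1L) seq_len(n_exons) else setdiff(seq_len(n_exons), k)
        gtf <- c(gtf, sprintf(
          "%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
          contig, ex_start0[use[1]] + 1L, ex_end0[use[length(use)]], strand,
          gid, tid, gid))
        for (e in use) {
          gtf <- c(gtf, sprintf(
            "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\"; exon_number \"%d\";",
            contig, ex_start0[e] + 1L, ex_end0[e], strand, gid, tid, gid, e))
        }
        # exon blocks in transcript order (5' -> 3' of the mRNA)
        ord <- if (strand == "+") use else rev(use)
        lens <- ex_len[ord]
        blocks <- data.frame(t_off = cumsum(c(0L, lens[-length(lens)])),
                             len = lens, g_start0 = ex_start0[ord],
                             strand = strand, contig = contig,
                             stringsAsFactors = FALSE)
        tx_exons[[tid]] <- blocks
        tx2chrom[tid] <- contig
        tx2gene[tid] <- gid
        tx_seq_plan[[tid]] <- list(contig = contig, strand = strand,
                                   starts0 = ex_start0[use], ends0 = ex_end0[use])
      }
    }
    genome <- vapply(contigs, function(cn) random_seq(offsets[[cn]] + 200L),
                     character(1))
    transcripts <- vapply(names(tx_seq_plan), function(tid) {
      pl <- tx_seq_plan[[tid]]
      s <- paste(substring(genome[[pl$contig]], pl$starts0 + 1L, pl$ends0),
                 collapse = "")
      if (pl$strand == "-") revcomp(s) else s
    }, character(1))
    ref <- structure(list(genome = genome, transcripts = transcripts,
                          gtf = gtf, tx2chrom = tx2chrom, tx2gene = tx2gene,
                          tx_exons = tx_exons, gene_meta = gene_meta),
                     class = "toy_reference")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(genome = file.path(out_dir, "genome.fa"),
                    gtf = file.path(out_dir, "annotation.gtf"),
                    transcripts = file.path(out_dir, "transcripts.fa"))
      gs <- Biostrings::DNAStringSet(genome)
      Biostrings::writeXStringSet(gs, paths$genome)
      ts <- Biostrings::DNAStringSet(transcripts)
      Biostrings::writeXStringSet(ts, paths$transcripts)
      writeLines(gtf, paths$gtf)
      ref$paths <- paths
    }
    ref
  })
}

#' @export
print.toy_reference <- function(x, ...) {
  cat(sprintf("<toy_reference> %d gene%s, %d transcript%s on %s\n",
              nrow(x$gene_meta), if (nrow(x$gene_meta) == 1) "" else "s",
              length(x$transcripts), if (length(x$transcripts) == 1) "" else "s",
              paste(names(x$genome), collapse = "+")))
  invisible(x)
}

#' Apply independent per-base sequencing errors to a sequence
#'
#' Each base independently suffers a substitution (to one of the three other
#' bases), an insertion of a random base after it, or a deletion, at the
#' given rates.
#'
#' @param seq nucleotide string.
#' @param sub_rate,ins_rate,del_rate per-base probabilities, summing to < 1.
#' @return list with `sequence` (mutated), `n_errors`, `positions` (1-based
#'   positions in the mutated sequence for substitutions/insertions; deleted
#'   bases are reported by their 1-based position in the input, negated) and
#'   `ops` (per-event codes `S`/`I`/`D`).
#' @export
corrupt_sequence <- function(seq, sub_rate = 0, ins_rate = 0, del_rate = 0) {
  out <- corrupt_reads(seq, paste(rep("I", nchar(seq)), collapse = ""),
                       sub_rate, ins_rate, del_rate)
  list(sequence = out$sequence[1], n_errors = out$n_errors[1],
       positions = out$positions[[1]], ops = out$ops[[1]])
}

# Vectorised error engine over read vectors, keeping qualities in lockstep:
# substituted/inserted bases get ERROR_Q qualities, others keep theirs.
corrupt_reads <- function(seqs, quals, sub_rate, ins_rate, del_rate) {
  n <- length(seqs)
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) {
    return(list(sequence = seqs, qualities = quals,
                n_errors = integer(n),
                positions = rep(list(integer(0)), n),
                ops = rep(list(character(0)), n),
                cum_out = lapply(nchar(seqs), seq_len)))
  }
  out_seq <- character(n); out_qual <- character(n)
  n_err <- integer(n)
  positions <- vector("list", n); opcodes <- vector("list", n)
  cum_out <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- strsplit(seqs[i], "")[[1]]
    qv <- phred_decode(quals[i])
    L <- length(ch)
    u <- stats::runif(L)
    op <- ifelse(u < sub_rate, "S",
          ifelse(u < sub_rate + del_rate, "D", "M"))
    ins_after <- stats::runif(L) < ins_rate
    pieces_c <- vector("list", L)
    pieces_q <- vector("list", L)
    pos <- integer(0); ops_i <- character(0)
    out_pos <- 0L; cum <- integer(L)
    for (j in seq_len(L)) {
      cj <- character(0); qj <- integer(0)
      if (op[j] == "M") {
        cj <- ch[j]; qj <- qv[j]
      } else if (op[j] == "S") {
        cj <- sample(setdiff(BASES, ch[j]), 1L)
        qj <- sample(ERROR_Q, 1L)
        pos <- c(pos, out_pos + 1L); ops_i <- c(ops_i, "S")
      } else {                      # deletion
        pos <- c(pos, -j); ops_i <- c(ops_i, "D")
      }
      if (ins_after[j]) {
        cj <- c(cj, sample(BASES, 1L))
        qj <- c(qj, sample(ERROR_Q, 1L))
        pos <- c(pos, out_pos + length(cj)); ops_i <- c(ops_i, "I")
      }
      out_pos <- out_pos + length(cj)
      cum[j] <- out_pos
      pieces_c[[j]] <- cj; pieces_q[[j]] <- qj
    }
    out_seq[i] <- paste(unlist(pieces_c), collapse = "")
    out_qual[i] <- phred_encode(unlist(pieces_q))
    n_err[i] <- length(ops_i)
    positions[[i]] <- pos; opcodes[[i]] <- ops_i
    cum_out[[i]] <- cum
  }
  list(sequence = out_seq, qualities = out_qual, n_errors = n_err,
       positions = positions, ops = opcodes, cum_out = cum_out)
}

# Distinct random k-mers with pairwise Hamming distance >= min_dist.
sample_separated_kmers <- function(n, k, min_dist = 4L) {
  picked <- character(0)
  mat <- NULL
  while (length(picked) < n) {
    cand <- random_seq(k)
    cb <- charToRaw(cand)
    if (!is.null(mat)) {
      d <- rowSums(mat != matrix(cb, nrow = nrow(mat), ncol = k, byrow = TRUE))
      if (any(d < min_dist)) next
    }
    picked <- c(picked, cand)
    mat <- rbind(mat, matrix(cb, nrow = 1))
  }
  picked
}

#' Simulate ONT-like single-cell reads with a known truth table
#'
#' Each read is adapter + cell barcode + UMI + poly-T + a transcript
#' fragment; every second read is emitted reverse-complemented. PCR
#' duplicates re-use a molecule's UMI and fragment; UMIs are distinct within
#' a cell. Errors are applied per base at the configured rates with
#' positions logged.
#'
#' @param params a [sim_params()].
#' @param reference a [make_toy_reference()] result (built from
#'   `params$n_genes`/`params$isoforms_per_gene` and `params$seed` when
#'   omitted).
#' @param out_dir optional directory; writes `reads.fastq`, `truth.csv`,
#'   `whitelist.txt` and the truth matrix under `truth_matrix/`.
#' @return list of class `ont_sim`: `reads` (read table), `truth`
#'   (read_id, cell_barcode, umi, transcript_id, gene_id, strand,
#'   n_errors_introduced, fragment_start, fragment_len), `cdna`/`cdna_qual`
#'   (corrupted fragment per read, mRNA orientation), `whitelist` (true
#'   barcodes with emitted-read counts), `truth_matrix` (gene-level
#'   `count_matrix` of distinct (cell, UMI, gene) molecules), `reference`,
#'   `params`, and `paths` when written.
#' @export
simulate_reads <- function(params = sim_params(), reference = NULL,
                           out_dir = NULL) {
  if (is.null(reference)) {
    reference <- make_toy_reference(params$n_genes, params$isoforms_per_gene,
                                    seed = params$seed)
  }
  chem <- params$chemistry
  with_seed(params$seed + 1L, {
    barcodes <- sample_separated_kmers(params$n_cells, chem$barcode_length)
    tx_ids <- names(reference$transcripts)
    tx_len <- nchar(reference$transcripts)
    mol <- list(); reads <- list()
    for (ci in seq_len(params$n_cells)) {
      n_mol <- max(1L, as.integer(round(params$reads_per_cell *
                                          (1 - params$dup_rate))))
      umis <- sample_separated_kmers(n_mol, params$umi_length, min_dist = 3L)
      tids <- sample(tx_ids, n_mol, replace = TRUE)
      frag_len <- pmin(tx_len[tids],
                       sample(200:450, n_mol, replace = TRUE))
      frag_start <- vapply(seq_len(n_mol), function(m) {
        if (tx_len[tids[m]] - frag_len[m] <= 0) 0L
        else sample.int(tx_len[tids[m]] - frag_len[m] + 1L, 1L) - 1L
      }, integer(1))
      pick <- sample.int(n_mol, params$reads_per_cell, replace = TRUE)
      mol[[ci]] <- data.frame(cell = ci, molecule = pick,
                              umi = umis[pick], transcript_id = tids[pick],
                              fragment_start = frag_start[pick],
                              fragment_len = frag_len[pick],
                              stringsAsFactors = FALSE)
    }
    mol <- do.call(rbind, mol)
    n_reads <- nrow(mol)
    read_id <- sprintf("read%06d", seq_len(n_reads))
    polyt <- strrep("T", sample(12:20, n_reads, replace = TRUE))
    cdna_clean <- substr(reference$transcripts[mol$transcript_id],
                         mol$fragment_start + 1L,
                         mol$fragment_start + mol$fragment_len)
    plain <- paste0(chem$adapter, barcodes[mol$cell], mol$umi, polyt,
                    cdna_clean)
    qual_clean <- vapply(nchar(plain), function(L) {
      phred_encode(sample(GOOD_Q, L, replace = TRUE))
    }, character(1))
    crp <- corrupt_reads(plain, qual_clean,
                         params$sub_rate, params$ins_rate, params$del_rate)
    seqs <- crp$sequence; quals <- crp$qualities
    strand <- rep(c("+", "-"), length.out = n_reads)
    flip <- strand == "-"
    seqs[flip] <- revcomp(seqs[flip])
    quals[flip] <- str_rev(quals[flip])
    reads <- data.frame(read_id = read_id, sequence = seqs,
                        qualities = quals, description = NA_character_,
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = read_id,
                        cell_barcode = barcodes[mol$cell],
                        umi = mol$umi,
                        transcript_id = mol$transcript_id,
                        gene_id = unname(reference$tx2gene[mol$transcript_id]),
                        strand = strand,
                        n_errors_introduced = crp$n_errors,
                        fragment_start = mol$fragment_start,
                        fragment_len = mol$fragment_len,
                        stringsAsFactors = FALSE)
    # corrupted cDNA in mRNA orientation, for perfect-placement alignments:
    # everything past the (error-free) structural prefix of the mutated read
    prefix_clean <- nchar(plain) - nchar(cdna_clean)
    cdna <- character(n_reads); cdna_qual <- character(n_reads)
    for (i in seq_len(n_reads)) {
      # output length of the structural prefix, mapped through any indels
      cut <- crp$cum_out[[i]][prefix_clean[i]]
      cdna[i] <- substr(crp$sequence[i], cut + 1L, nchar(crp$sequence[i]))
      cdna_qual[i] <- substr(crp$qualities[i], cut + 1L,
                             nchar(crp$qualities[i]))
    }
    whitelist <- data.frame(barcode = barcodes,
                            count = as.integer(table(factor(mol$cell,
                              levels = seq_len(params$n_cells)))),
                            stringsAsFactors = FALSE)
    whitelist <- whitelist[order(-whitelist$count, whitelist$barcode), ]
    whitelist$rank <- seq_len(nrow(whitelist))
    rownames(whitelist) <- NULL
    truth_matrix <- truth_gene_matrix(truth, reference)
    sim <- structure(list(reads = reads, truth = truth,
                          cdna = cdna, cdna_qual = cdna_qual,
                          whitelist = whitelist, truth_matrix = truth_matrix,
                          reference = reference, params = params),
                     class = "ont_sim")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(fastq = file.path(out_dir, "reads.fastq"),
                    truth = file.path(out_dir, "truth.csv"),
                    whitelist = file.path(out_dir, "whitelist.txt"),
                    truth_matrix = file.path(out_dir, "truth_matrix"))
      write_fastq(reads, paths$fastq)
      utils::write.csv(truth, paths$truth, row.names = FALSE)
      write_whitelist(whitelist, paths$whitelist)
      write_matrix(truth_matrix, paths$truth_matrix)
      sim$paths <- paths
    }
    sim
  })
}

# Gene-level truth matrix: one count per distinct (cell, UMI, gene) molecule.
truth_gene_matrix <- function(truth, reference) {
  key <- unique(truth[, c("cell_barcode", "umi", "gene_id")])
  counts <- stats::aggregate(list(count = key$umi),
                             by = list(barcode = key$cell_barcode,
                                       feature_id = key$gene_id),
                             FUN = length)
  meta <- reference$gene_meta
  features <- data.frame(feature_id = meta$gene_id,
                         feature_name = meta$gene_name, kind = "gene",
                         stringsAsFactors = FALSE)
  count_matrix(counts, features,
               barcodes = sort(unique(truth$cell_barcode)))
}

#' @export
print.ont_sim <- function(x, ...) {
  cat(sprintf(
    "<ont_sim> %d reads from %d cells (%d molecules); sub/ins/del = %g/%g/%g\n",
    nrow(x$reads), x$params$n_cells, as.integer(sum(x$truth_matrix$matrix)),
    x$params$sub_rate, x$params$ins_rate, x$params$del_rate))
  invisible(x)
}

# Map a transcript interval [a, b) (0-based) through a transcript's exon
# blocks to genomic blocks; returns data.frame(start0, end0) sorted by
# genomic start.
tx_interval_to_genome <- function(blocks, a, b) {
  out <- list()
  for (e in seq_len(nrow(blocks))) {
    t0 <- blocks$t_off[e]; t1 <- t0 + blocks$len[e]
    lo <- max(a, t0); hi <- min(b, t1)
    if (lo >= hi) next
    if (blocks$strand[e] == "+") {
      g0 <- blocks$g_start0[e] + (lo - t0)
      g1 <- blocks$g_start0[e] + (hi - t0)
    } else {
      g0 <- blocks$g_start0[e] + blocks$len[e] - (hi - t0)
      g1 <- blocks$g_start0[e] + blocks$len[e] - (lo - t0)
    }
    out[[length(out) + 1L]] <- c(g0, g1)
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start0 = m[, 1], end0 = m[, 2])
}

#' Perfect-placement alignments for simulated reads
#'
#' Emits one primary SAM record per read at its true origin. Transcriptome
#' mode places the (corrupted) cDNA on its transcript; genome mode uses
#' spliced placement with `N` gaps across introns and the mRNA strand of the
#' gene. Length changes from indels are absorbed by soft-clipping surplus
#' bases (or shortening the final block) at the transcript-3' end, keeping
#' the CIGAR consistent with the stored sequence and the 5' position stable
#' across PCR duplicates.
#'
#' @param sim an [simulate_reads()] result.
#' @param mode `"genome"` or `"transcriptome"`.
#' @param out optional SAM path.
#' @return a `sam_set` (coordinate-sorted), written to `out` when given.
#' @export
simulate_alignments <- function(sim, mode = c("genome", "transcriptome"),
                                out = NULL) {
  mode <- match.arg(mode)
  ref <- sim$reference
  truth <- sim$truth
  n <- nrow(truth)
  L_obs <- nchar(sim$cdna)
  m_len <- pmin(L_obs, truth$fragment_len)
  extra <- pmax(L_obs - truth$fragment_len, 0L)
  if (mode == "transcriptome") {
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(ref$transcripts),
                        nchar(ref$transcripts)))
    cigar <- paste0(m_len, "M", ifelse(extra > 0, paste0(extra, "S"), ""))
    rec <- data.frame(qname = truth$read_id, flag = 0L,
                      rname = truth$transcript_id,
                      pos = truth$fragment_start + 1L, mapq = 60L,
                      cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
                      seq = sim$cdna, qual = sim$cdna_qual, tags = "",
                      stringsAsFactors = FALSE)
  } else {
    glen <- nchar(ref$genome)
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome), glen))
    rname <- character(n); pos <- integer(n); cigar <- character(n)
    flag <- integer(n); seqs <- character(n); quals <- character(n)
    for (i in seq_len(n)) {
      blocks <- ref$tx_exons[[truth$transcript_id[i]]]
      gstrand <- blocks$strand[1]
      gb <- tx_interval_to_genome(blocks, truth$fragment_start[i],
                                  truth$fragment_start[i] + m_len[i])
      widths <- gb$end0 - gb$start0
      core <- paste0(widths, "M")
      if (nrow(gb) > 1) {
        gaps <- gb$start0[-1] - gb$end0[-nrow(gb)]
        core <- paste0(core, c(paste0(gaps, "N"), ""))
      }
      core <- paste(core, collapse = "")
      sclip <- if (extra[i] > 0) paste0(extra[i], "S") else ""
      if (gstrand == "+") {
        cigar[i] <- paste0(core, sclip)
        seqs[i] <- sim$cdna[i]; quals[i] <- sim$cdna_qual[i]
        flag[i] <- 0L
      } else {
        cigar[i] <- paste0(sclip, core)
        seqs[i] <- revcomp(sim$cdna[i]); quals[i] <- str_rev(sim$cdna_qual[i])
        flag[i] <- 16L
      }
      rname[i] <- blocks$contig[1]
      pos[i] <- gb$start0[1] + 1L
    }
    rec <- data.frame(qname = truth$read_id, flag = flag, rname = rname,
                      pos = pos, mapq = 60L, cigar = cigar, rnext = "*",
                      pnext = 0L, tlen = 0L, seq = seqs, qual = quals,
                      tags = "", stringsAsFactors = FALSE)
  }
  rec <- rec[order(rec$rname, rec$pos, rec$qname), , drop = FALSE]
  rownames(rec) <- NULL
  sam <- structure(list(header = header, records = rec), class = "sam_set")
  if (!is.null(out)) write_sam(sam, out)
  sam
}
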