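# Per-cell UMI deduplication. Alignments are grouped into locus groups
# (cell barcode x soft-clip-adjusted 5' position in genome mode, cell
# barcode x transcript in transcriptome mode); within a group, UMIs are
# clustered by the directional network rule and one representative alignment
# is kept per cluster.

#' Deduplication parameters
#'
#' @param method `"directional"` (UMI network clustering with the
#'   `count(a) >= 2*count(b) - 1` merge rule) or `"unique"` (every distinct
#'   UMI is its own molecule, MarkDuplicates-like).
#' @param umi_hamming maximum Hamming distance for a directional edge
#'   (default 1).
#' @param mode `"genome"` (locus = contig, strand, adjusted 5' position) or
#'   `"transcriptome"` (locus = transcript id).
#' @return a `dedup_params` list.
#' @export
dedup_params <- function(method = c("directional", "unique"),
                         umi_hamming = 1L,
                         mode = c("genome", "transcriptome")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(umi_hamming >= 0L)
  structure(list(method = method, umi_hamming = as.integer(umi_hamming),
                 mode = mode),
            class = "dedup_params")
}

#' Group alignments into deduplication locus groups
#'
#' Only primary, mapped, `CB`-tagged records are grouped; a `CB`-tagged
#' record lacking a `UR` tag is an error. Genome mode keys on
#' (CB, contig, strand, soft-clip-adjusted 5' position); transcriptome mode
#' on (CB, transcript).
#'
#' @param sam `sam_set` (or SAM/BAM path).
#' @param mode `"genome"` or `"transcriptome"`.
#' @return list with `keys` (data.frame of group keys), `groups` (list of
#'   record row-index vectors, parallel to `keys`), `umis` (per-record UMI
#'   vector) and `eligible` (logical over input records).
#' @export
group_alignments <- function(sam, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  if (is.character(sam)) sam <- read_sam(sam)
  rec <- sam$records
  cb <- sam_get_tag(rec$tags, "CB")
  ur <- sam_get_tag(rec$tags, "UR")
  eligible <- !is.na(cb) & flag_is_primary(rec$flag) & !flag_is_unmapped(rec$flag)
  bad <- eligible & is.na(ur)
  if (any(bad)) {
    stop("CB-tagged record(s) missing UR tag: ",
         paste(utils::head(rec$qname[bad], 10), collapse = ", "))
  }
  idx <- which(eligible)
  if (mode == "genome") {
    key <- data.frame(cell_barcode = cb[idx], contig = rec$rname[idx],
                      strand = ifelse(flag_is_reverse(rec$flag[idx]), "-", "+"),
                      pos5 = fivep_position(rec$flag[idx], rec$pos[idx],
                                            rec$cigar[idx]),
                      stringsAsFactors = FALSE)
    kstr <- paste(key$cell_barcode, key$contig, key$strand, key$pos5, sep = "\r")
  } else {
    key <- data.frame(cell_barcode = cb[idx], transcript = rec$rname[idx],
                      stringsAsFactors = FALSE)
    kstr <- paste(key$cell_barcode, key$transcript, sep = "\r")
  }
  groups <- split(idx, kstr)
  first <- vapply(split(seq_along(idx), kstr), `[`, integer(1), 1)
  list(keys = key[first, , drop = FALSE],
       groups = groups,
       umis = ur,
       eligible = eligible)
}

#' Cluster UMIs with the directional network rule
#'
#' Builds the directed graph with an edge `a -> b` whenever
#' `hamming(a, b) <= umi_hamming` and `count(a) >= 2*count(b) - 1`, then
#' peels clusters: nodes are visited in count-descending (then lexicographic)
#' order, and each unclaimed node seeds a cluster containing every unclaimed
#' node reachable from it.
#'
#' @param umi_counts named integer vector (UMI -> read count), uniform UMI
#'   length.
#' @param umi_hamming maximum Hamming distance for an edge (default 1).
#' @return list of clusters, each a list with `representative_umi` (the
#'   member with maximal count, ties lexicographic), `member_umis` (named
#'   count vector) and `n_reads`.
#' @export
cluster_umis_directional <- function(umi_counts, umi_hamming = 1L) {
  umis <- names(umi_counts)
  if (length(umis) == 0) return(list())
  if (length(unique(nchar(umis))) > 1) stop("mixed UMI lengths")
  counts <- as.integer(umi_counts)
  ord <- order(-counts, umis)
  umis <- umis[ord]; counts <- counts[ord]
  n <- length(umis)
  # pairwise Hamming distances on the (small) per-locus UMI set
  if (n > 1) {
    chars <- matrix(unlist(lapply(umis, charToRaw)), nrow = n, byrow = TRUE)
    adj <- lapply(seq_len(n), function(i) {
      d <- rowSums(chars != matrix(chars[i, ], nrow = n, ncol = ncol(chars),
                                   byrow = TRUE))
      which(d <= umi_hamming & d > 0 & counts[i] >= 2L * counts - 1L)
    })
  } else {
    adj <- list(integer(0))
  }
  claimed <- rep(FALSE, n)
  clusters <- list()
  for (s in seq_len(n)) {
    if (claimed[s]) next
    members <- s; claimed[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!claimed[nxt]]
      claimed[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt
    }
    members <- sort(members)
    mem_counts <- stats::setNames(counts[members], umis[members])
    clusters[[length(clusters) + 1L]] <- list(
      representative_umi = umis[members[1]],  # maximal count, lexicographic tie
      member_umis = mem_counts,
      n_reads = sum(mem_counts))
  }
  clusters
}

#' Pick the representative alignment of a duplicate set
#'
#' Deterministic: highest MAPQ, then longest aligned reference span, then
#' smallest read id.
#'
#' @param records data.frame of alignment records (rows of a `sam_set`).
#' @return the selected row (single-row data.frame).
#' @export
select_representative <- function(records) {
  stopifnot(nrow(records) > 0)
  span <- cigar_ref_span(records$cigar)
  ord <- order(-records$mapq, -span, records$qname)
  records[ord[1], , drop = FALSE]
}

#' Deduplicate a tagged alignment file by UMI
#'
#' @param bam_in tagged SAM/BAM path or `sam_set` (must carry `CB`/`UR`
#'   tags; an input with no tags at all is rejected with a pointer to
#'   [tag_bam()]).
#' @param params a [dedup_params()].
#' @param out optional output SAM/BAM path.
#' @return list with `sam` (one record per molecule, input order — hence
#'   coordinate order — preserved), `out`, `stats` (`n_in`, `n_out`,
#'   `n_molecules`) and `group_stats` (per-locus-group data.frame:
#'   key columns, `n_in`, `n_out`).
#' @export
dedup_bam <- function(bam_in, params = dedup_params(), out = NULL) {
  sam <- if (is.character(bam_in)) read_sam(bam_in) else bam_in
  rec <- sam$records
  if (nrow(rec) > 0 && all(is.na(sam_get_tag(rec$tags, "CB"))) &&
      all(is.na(sam_get_tag(rec$tags, "CR")))) {
    stop("input carries no barcode tags; run tag_bam() before dedup_bam()")
  }
  grp <- group_alignments(sam, params$mode)
  keep_rows <- integer(0)
  g_n_in <- integer(length(grp$groups))
  g_n_out <- integer(length(grp$groups))
  for (gi in seq_along(grp$groups)) {
    rows <- grp$groups[[gi]]
    umis <- grp$umis[rows]
    if (params$method == "directional") {
      clusters <- cluster_umis_directional(
        table_counts(umis), params$umi_hamming)
      member_sets <- lapply(clusters, function(cl) names(cl$member_umis))
    } else {
      member_sets <- as.list(sort(unique(umis)))
    }
    for (ms in member_sets) {
      cand <- rows[umis %in% ms]
      rep_row <- select_representative(rec[cand, , drop = FALSE])
      keep_rows <- c(keep_rows, cand[match(rep_row$qname, rec$qname[cand])])
    }
    g_n_in[gi] <- length(rows)
    g_n_out[gi] <- length(member_sets)
  }
  keep_rows <- sort(keep_rows)
  out_sam <- structure(list(header = sam$header,
                            records = rec[keep_rows, , drop = FALSE]),
                       class = "sam_set")
  if (!is.null(out)) write_sam(out_sam, out)
  gstats <- cbind(grp$keys, n_in = g_n_in, n_out = g_n_out)
  rownames(gstats) <- NULL
  list(sam = out_sam, out = out,
       stats = list(n_in = nrow(rec), n_out = length(keep_rows),
                    n_molecules = length(keep_rows)),
       group_stats = gstats)
}

table_counts <- function(x) {
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}
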