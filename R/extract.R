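# Read-structure parsing: find the adapter on either strand by semi-global
# edit distance, lay the barcode and UMI spans out behind it, record any
# poly-T run, and emit a barcode-free read plus a putative-barcode record.
# All intervals are 0-based half-open.

# Batch adapter search by semi-global edit distance (substitutions + indels;
# the adapter is aligned in full, the window start and end are free). A
# column-wise Needleman-Wunsch band is advanced over all windows at once, so
# cost is O(window x adapter) vector operations regardless of read count.
# For each window the minimal distance wins, ties broken by the most 5' end.
# Returns end offset (0-based, one past the adapter) and distance, NA when
# the best distance exceeds max_dist.
adapter_scan <- function(windows, adapter, max_dist) {
  n <- length(windows)
  if (n == 0) return(data.frame(end0 = integer(0), dist = integer(0)))
  pat <- strsplit(adapter, "")[[1]]
  P <- length(pat)
  lens <- nchar(windows)
  maxw <- max(lens, 0L)
  if (maxw == 0L) {
    return(data.frame(end0 = rep(NA_integer_, n), dist = rep(NA_integer_, n)))
  }
  cm <- matrix("", n, maxw)
  sp <- strsplit(windows, "")
  for (i in seq_len(n)) if (lens[i] > 0) cm[i, seq_len(lens[i])] <- sp[[i]]
  big <- P + maxw + 1L
  D <- matrix(rep(0:P, n), P + 1L, n)  # j = 0: adapter prefix vs nothing
  D[1, ] <- 0L                         # free start
  best_d <- rep(big, n)
  best_e <- rep(NA_integer_, n)
  for (j in seq_len(maxw)) {
    ch <- cm[, j]
    newD <- D                 # will overwrite rows 2..P+1
    newD[1, ] <- 0L
    for (i in seq_len(P)) {
      cost <- ifelse(ch == pat[i], 0L, 1L)
      newD[i + 1L, ] <- pmin(D[i, ] + cost,       # sub/match
                             D[i + 1L, ] + 1L,    # insertion in window
                             newD[i, ] + 1L)      # deletion from window
    }
    final <- newD[P + 1L, ]
    upd <- j <= lens & final < best_d
    best_d[upd] <- final[upd]
    best_e[upd] <- j
    D <- newD
    if (j >= P && all(best_d == 0L)) break  # cannot improve further
  }
  hit <- best_d <= max_dist
  data.frame(end0 = ifelse(hit, best_e, NA_integer_),
             dist = ifelse(hit, best_d, NA_integer_))
}

# Longest valid poly-T run starting at 0-based offset `start0`: at most one
# non-T per 10 bases, never 3 non-T in a row, must end on a T and reach
# `min_run`. Returns the 0-based offset one past the run, or NA.
polyt_scan <- function(seq, start0, min_run) {
  chars <- charToRaw(substr(seq, start0 + 1L, nchar(seq)))
  if (length(chars) == 0) return(NA_integer_)
  is_t <- chars == charToRaw("T")
  non_t <- 0L; consec <- 0L; best <- NA_integer_
  for (i in seq_along(is_t)) {
    if (is_t[i]) {
      consec <- 0L
      if (i >= min_run && non_t * 10L <= i) best <- i
    } else {
      non_t <- non_t + 1L
      consec <- consec + 1L
      if (consec >= 3L) break
    }
  }
  if (is.na(best)) NA_integer_ else start0 + best
}

# Vectorised structure location over a read table. Returns one row per read:
# found, strand, dist, adapter_end, bc_start/bc_end, umi_start/umi_end,
# polyt_end (offsets on the oriented read).
locate_structure_batch <- function(reads, chem) {
  n <- nrow(reads)
  if (n == 0) {
    return(data.frame(found = logical(0), strand = character(0),
                      dist = integer(0), adapter_end = integer(0),
                      bc_start = integer(0), bc_end = integer(0),
                      umi_start = integer(0), umi_end = integer(0),
                      polyt_end = integer(0)))
  }
  win <- chem$search_window
  fwd <- substr(reads$sequence, 1L, pmin(nchar(reads$sequence), win))
  rcseq <- revcomp(reads$sequence)
  rev <- substr(rcseq, 1L, pmin(nchar(rcseq), win))
  hf <- adapter_scan(fwd, chem$adapter, chem$max_adapter_edit_distance)
  hr <- adapter_scan(rev, chem$adapter, chem$max_adapter_edit_distance)
  # prefer the lower-distance strand; ties go to "+"
  use_rev <- !is.na(hr$dist) & (is.na(hf$dist) | hr$dist < hf$dist)
  strand <- ifelse(use_rev, "-", "+")
  dist <- ifelse(use_rev, hr$dist, hf$dist)
  aend <- ifelse(use_rev, hr$end0, hf$end0)
  found <- !is.na(aend)
  bc_start <- aend
  bc_end <- bc_start + chem$barcode_length
  umi_start <- bc_end
  umi_end <- umi_start + chem$umi_length
  # spans must fit on the read
  found <- found & !is.na(umi_end) & umi_end <= nchar(reads$sequence)
  polyt_end <- rep(NA_integer_, n)
  for (i in which(found)) {
    s <- if (strand[i] == "-") rcseq[i] else reads$sequence[i]
    polyt_end[i] <- polyt_scan(s, umi_end[i], chem$polyt_min_run)
  }
  data.frame(found = found, strand = strand, dist = dist,
             adapter_end = aend, bc_start = bc_start, bc_end = bc_end,
             umi_start = umi_start, umi_end = umi_end, polyt_end = polyt_end)
}

#' Locate the 10X read structure on a single read
#'
#' Searches both the read and its reverse complement for the chemistry's
#' adapter within `search_window` bases of the start, tolerating up to
#' `max_adapter_edit_distance` substitutions/indels, and lays out the barcode
#' and UMI spans immediately behind the best (lowest-distance, most 5') hit.
#' A poly-T run directly after the UMI (at most one non-T per 10 bases) is
#' recorded when present; its absence does not reject the read.
#'
#' @param read single-row read table or list with `sequence`, `qualities`.
#' @param chem a [chemistry_profile()].
#' @return a `structure_hit` list (`strand`, `adapter_dist`, `adapter_end`,
#'   `bc_start`, `bc_end`, `umi_start`, `umi_end`, `polyt_end`; offsets are
#'   0-based half-open on the oriented read), or `NULL` when no adapter match
#'   is found or the spans do not fit.
#' @export
locate_structure <- function(read, chem) {
  df <- as.data.frame(read, stringsAsFactors = FALSE)
  h <- locate_structure_batch(df[1, , drop = FALSE], chem)
  if (!h$found[1]) return(NULL)
  structure(list(strand = h$strand[1], adapter_dist = h$dist[1],
                 adapter_end = h$adapter_end[1],
                 bc_start = h$bc_start[1], bc_end = h$bc_end[1],
                 umi_start = h$umi_start[1], umi_end = h$umi_end[1],
                 polyt_end = h$polyt_end[1]),
            class = "structure_hit")
}

#' Extract the barcode/UMI and emit the barcode-free read
#'
#' Orients the read by the hit strand, slices out barcode and UMI with their
#' quality substrings, and trims everything through the UMI (and through the
#' poly-T run when one was found), leaving the cDNA suffix for alignment.
#'
#' @param read single-row read table or list.
#' @param hit a `structure_hit` from [locate_structure()].
#' @param chem the [chemistry_profile()] used to locate the hit.
#' @return list with `trimmed` (read table row) and `record` (putative
#'   barcode row: `read_id`, `barcode`, `barcode_quals`, `umi`, `umi_quals`,
#'   `strand`).
#' @export
extract_read <- function(read, hit, chem) {
  read <- as.data.frame(read, stringsAsFactors = FALSE)[1, ]
  seq <- read$sequence; qual <- read$qualities
  if (hit$strand == "-") {
    seq <- revcomp(seq)
    qual <- str_rev(qual)
  }
  trim_from <- if (!is.na(hit$polyt_end)) hit$polyt_end else hit$umi_end
  if (hit$bc_start < 0 || hit$umi_end > nchar(seq) || trim_from > nchar(seq)) {
    stop("structure hit spans fall outside read '", read$read_id, "'")
  }
  trimmed <- data.frame(
    read_id = read$read_id,
    sequence = substr(seq, trim_from + 1L, nchar(seq)),
    qualities = substr(qual, trim_from + 1L, nchar(qual)),
    description = if ("description" %in% names(read)) read$description else NA_character_,
    stringsAsFactors = FALSE)
  record <- data.frame(
    read_id = read$read_id,
    barcode = substr(seq, hit$bc_start + 1L, hit$bc_end),
    barcode_quals = substr(qual, hit$bc_start + 1L, hit$bc_end),
    umi = substr(seq, hit$umi_start + 1L, hit$umi_end),
    umi_quals = substr(qual, hit$umi_start + 1L, hit$umi_end),
    strand = hit$strand,
    stringsAsFactors = FALSE)
  list(trimmed = trimmed, record = record)
}

#' Run structure extraction over a whole FASTQ
#'
#' Emits one barcode-free FASTQ record and one putative-barcode table row per
#' read whose structure was found. When a putative-barcode table from an
#' upstream detector is supplied, extraction is cross-checked against it:
#' rows whose extracted barcode differs from the putative one by edit
#' distance > 1 are counted as discordant.
#'
#' @param fastq_in input FASTQ path.
#' @param chem a [chemistry_profile()].
#' @param out_fastq output path for the barcode-free FASTQ.
#' @param out_table output path for the barcode/UMI CSV (columns
#'   `read_id,barcode,barcode_quals,umi,umi_quals,strand`).
#' @param putative_table optional path to an upstream putative-barcode CSV
#'   with columns `read_id`, `putative_bc`, `putative_bc_min_q` (header
#'   required; unknown columns ignored).
#' @param strict when `TRUE`, structured reads missing from `putative_table`
#'   are an error (offenders listed) instead of being skipped in the
#'   cross-check.
#' @param min_mean_quality,min_length,max_length optional read filter applied
#'   before extraction (see [filter_reads()]); defaults leave filtering off.
#' @return list with `fastq_out`, `table_out` and `stats` (`n_input`,
#'   `n_filtered_out`, `n_structured`, `n_unstructured`, `n_with_polyt`,
#'   `n_discordant`).
#' @export
extract_batch <- function(fastq_in, chem, out_fastq, out_table,
                          putative_table = NULL, strict = FALSE,
                          min_mean_quality = 0, min_length = 1L,
                          max_length = .Machine$integer.max) {
  reads <- read_fastq(fastq_in)
  n_raw <- nrow(reads)
  flt <- filter_reads(reads, min_mean_quality, min_length, max_length)
  reads <- flt$kept
  hits <- locate_structure_batch(reads, chem)
  keep <- which(hits$found)
  trimmed <- vector("list", length(keep))
  records <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    hit <- structure(list(strand = hits$strand[i], adapter_dist = hits$dist[i],
                          adapter_end = hits$adapter_end[i],
                          bc_start = hits$bc_start[i], bc_end = hits$bc_end[i],
                          umi_start = hits$umi_start[i], umi_end = hits$umi_end[i],
                          polyt_end = hits$polyt_end[i]),
                     class = "structure_hit")
    ex <- extract_read(reads[i, ], hit, chem)
    trimmed[[j]] <- ex$trimmed
    records[[j]] <- ex$record
  }
  trimmed <- if (length(trimmed)) do.call(rbind, trimmed) else
    data.frame(read_id = character(0), sequence = character(0),
               qualities = character(0), description = character(0))
  records <- if (length(records)) do.call(rbind, records) else
    empty_barcode_table()
  n_discordant <- 0L
  if (!is.null(putative_table)) {
    put <- utils::read.csv(putative_table, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("read_id", "putative_bc")
    if (!all(need %in% names(put))) {
      stop("putative table missing column(s): ",
           paste(setdiff(need, names(put)), collapse = ", "))
    }
    m <- match(records$read_id, put$read_id)
    if (strict && anyNA(m)) {
      stop("read id(s) absent from putative table: ",
           paste(utils::head(records$read_id[is.na(m)], 10), collapse = ", "))
    }
    have <- !is.na(m)
    if (any(have)) {
      d <- mapply(function(a, b) utils::adist(a, b)[1, 1],
                  records$barcode[have], put$putative_bc[m[have]])
      n_discordant <- sum(d > 1L)
    }
  }
  write_fastq(trimmed, out_fastq)
  write_barcode_table(records, out_table)
  list(fastq_out = out_fastq, table_out = out_table,
       stats = list(n_input = n_raw,
                    n_filtered_out = flt$n_dropped,
                    n_structured = length(keep),
                    n_unstructured = nrow(reads) - length(keep),
                    n_with_polyt = sum(!is.na(hits$polyt_end[keep])),
                    n_discordant = n_discordant))
}

empty_barcode_table <- function() {
  data.frame(read_id = character(0), barcode = character(0),
             barcode_quals = character(0), umi = character(0),
             umi_quals = character(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Write / read the putative-barcode table
#'
#' CSV with header `read_id,barcode,barcode_quals,umi,umi_quals,strand`;
#' qualities are Phred+33 strings. Correction appends
#' `corrected_barcode,posterior,status`.
#' @param tab barcode table.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_barcode_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_barcode_table
#' @export
read_barcode_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("read_id", "barcode", "barcode_quals", "umi", "umi_quals")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("barcode table missing column(s): ", paste(miss, collapse = ", "))
  }
  if ("posterior" %in% names(tab)) {
    tab$posterior <- suppressWarnings(as.numeric(tab$posterior))
  }
  tab
}
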