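# Whitelist construction and Bayesian barcode correction.
#
# Putative barcodes are ranked by abundance among high-quality observations;
# the whitelist is the head of that ranking (expected-cells quantile rule, or
# a knee on the log-log rank/abundance curve). Each observed barcode is then
# compared to its Hamming-<=2 whitelist neighbourhood and assigned the
# candidate maximising prior(abundance) x likelihood(quality-weighted
# mismatches); corrections are accepted at posterior >= 97.5%.

#' Hamming distance between two equal-length strings
#'
#' @param a,b character scalars of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming_distance: unequal lengths")
  sum(charToRaw(a) != charToRaw(b))
}

#' Correction parameters
#'
#' @param max_hamming maximum Hamming distance to a whitelist candidate
#'   (default 2).
#' @param posterior_threshold acceptance threshold on the winning posterior
#'   (default 0.975).
#' @param prior_pseudocount added to whitelist abundances in the prior
#'   (default 1, avoiding zero priors).
#' @param min_whitelist_quality minimum per-base barcode quality for an
#'   observation to count towards whitelist abundances (default 15).
#' @return a `correction_params` list.
#' @export
correction_params <- function(max_hamming = 2L, posterior_threshold = 0.975,
                              prior_pseudocount = 1, min_whitelist_quality = 15L) {
  stopifnot(max_hamming >= 0L, posterior_threshold > 0,
            posterior_threshold <= 1, prior_pseudocount >= 0)
  structure(list(max_hamming = as.integer(max_hamming),
                 posterior_threshold = posterior_threshold,
                 prior_pseudocount = prior_pseudocount,
                 min_whitelist_quality = as.integer(min_whitelist_quality)),
            class = "correction_params")
}

#' Rank putative barcodes by abundance
#'
#' Counts barcodes over records whose minimum barcode base quality reaches
#' `min_quality`, then orders by count descending with the lexicographically
#' smaller barcode first on ties.
#'
#' @param records putative-barcode table ([read_barcode_table()]).
#' @param min_quality Phred floor on the per-base barcode quality.
#' @return data.frame `barcode`, `count`, `rank`.
#' @export
rank_barcodes <- function(records, min_quality = 15L) {
  if (nrow(records) == 0) return(empty_whitelist())
  minq <- vapply(records$barcode_quals,
                 function(q) if (nzchar(q)) min(phred_decode(q)) else 0L,
                 integer(1), USE.NAMES = FALSE)
  bc <- records$barcode[minq >= min_quality]
  if (length(bc) == 0) return(empty_whitelist())
  tab <- table(bc)
  df <- data.frame(barcode = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$barcode), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

empty_whitelist <- function() {
  data.frame(barcode = character(0), count = integer(0), rank = integer(0),
             stringsAsFactors = FALSE)
}

# Kneedle-style knee: on the log10 rank / log10 count curve, the knee is the
# point furthest below the chord joining the endpoints.
knee_rank <- function(counts) {
  n <- length(counts)
  if (n <= 2) return(n)
  x <- log10(seq_len(n))
  y <- log10(pmax(counts, 1L))
  xs <- (x - x[1]) / (x[n] - x[1])
  drop <- (y[1] - y) / (y[1] - y[n])  # 0 at start, 1 at end, larger = dropped more
  which.max(drop - xs)                # furthest below the normalised diagonal
}

#' Build the cell whitelist from ranked barcodes
#'
#' With `expected_cells` supplied, the abundance threshold is the count at
#' rank `ceiling(0.05 * expected_cells)` divided by 20, and barcodes counted
#' strictly above it are kept (the quantile convention of droplet cell
#' callers). Without it, the knee of the log-log rank/abundance curve is
#' located and ranks up to the knee are kept.
#'
#' @param ranked output of [rank_barcodes()].
#' @param expected_cells expected number of real cells, or `NULL` for knee
#'   detection.
#' @return subset of `ranked` (the whitelist), ranking preserved.
#' @export
build_whitelist <- function(ranked, expected_cells = NULL) {
  if (nrow(ranked) == 0) return(ranked)
  if (!is.null(expected_cells)) {
    expected_cells <- as.integer(expected_cells)
    if (expected_cells > nrow(ranked)) {
      stop("expected_cells (", expected_cells, ") exceeds number of ranked barcodes (",
           nrow(ranked), ")")
    }
    anchor <- max(1L, as.integer(ceiling(0.05 * expected_cells)))
    threshold <- ranked$count[anchor] / 20
    keep <- ranked$count > threshold
  } else {
    keep <- ranked$rank <= knee_rank(ranked$count)
  }
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a whitelist file
#'
#' Plain text, one barcode per line with an optional tab-separated count
#' column.
#' @param wl whitelist data.frame (`barcode`, optional `count`).
#' @param path file path.
#' @return `path` (write) or a whitelist data.frame (read; absent counts
#'   become 0 and ranks follow file order).
#' @export
write_whitelist <- function(wl, path) {
  lines <- if ("count" %in% names(wl)) paste(wl$barcode, wl$count, sep = "\t")
           else wl$barcode
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_whitelist())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bc <- vapply(parts, `[`, character(1), 1)
  cnt <- vapply(parts, function(p) {
    if (length(p) >= 2) as.integer(p[2]) else 0L
  }, integer(1))
  data.frame(barcode = bc, count = cnt, rank = seq_along(bc),
             stringsAsFactors = FALSE)
}

# Pre-split whitelist barcodes into a raw byte matrix for vectorised
# Hamming queries; cached on the data.frame.
whitelist_matrix <- function(whitelist) {
  attr_m <- attr(whitelist, "bc_matrix")
  if (!is.null(attr_m)) return(attr_m)
  L <- unique(nchar(whitelist$barcode))
  if (length(L) > 1) stop("whitelist barcodes have mixed lengths")
  matrix(unlist(lapply(whitelist$barcode, charToRaw)),
         nrow = nrow(whitelist), ncol = L, byrow = TRUE)
}

#' Whitelist entries within Hamming distance d of a query
#'
#' @param query barcode string.
#' @param whitelist whitelist data.frame (`barcode`, `count`).
#' @param d maximum Hamming distance.
#' @return subset of `whitelist` with an added `distance` column, whitelist
#'   order preserved; equivalent to an exhaustive linear scan.
#' @export
candidates_within <- function(query, whitelist, d = 2L) {
  if (nrow(whitelist) == 0) {
    out <- whitelist; out$distance <- integer(0); return(out)
  }
  m <- whitelist_matrix(whitelist)
  if (nchar(query) != ncol(m)) stop("query length differs from whitelist barcode length")
  qb <- matrix(charToRaw(query), nrow = nrow(m), ncol = ncol(m), byrow = TRUE)
  dist <- rowSums(m != qb)
  keep <- dist <= d
  out <- whitelist[keep, , drop = FALSE]
  out$distance <- as.integer(dist[keep])
  rownames(out) <- NULL
  out
}

#' Posterior probability of each candidate barcode
#'
#' For candidate `c`, the likelihood of the observed barcode is the product
#' over positions of `p_i/3` at mismatches and `1 - p_i` at matches, with
#' `p_i = 10^(-Q_i/10)` from the observed base qualities (uniform
#' substitution model). The prior is proportional to the candidate's
#' whitelist abundance plus `prior_pseudocount`, and posteriors are
#' normalised over the candidate set.
#'
#' @param observed observed barcode string.
#' @param quals Phred+33 quality string (or integer vector) for `observed`.
#' @param candidates candidate whitelist subset ([candidates_within()]).
#' @param params a [correction_params()].
#' @return numeric vector of posteriors aligned with `candidates` rows
#'   (empty for an empty candidate set; all-`NaN` likelihood mass degrades to
#'   a zero vector).
#' @export
barcode_posterior <- function(observed, quals, candidates,
                              params = correction_params()) {
  if (nrow(candidates) == 0) return(numeric(0))
  q <- if (is.character(quals)) phred_decode(quals) else as.integer(quals)
  stopifnot(length(q) == nchar(observed))
  p <- 10^(-q / 10)
  obs <- charToRaw(observed)
  log_match <- log(pmax(1 - p, 0))
  log_mis <- log(p / 3)
  loglik <- vapply(candidates$barcode, function(cand) {
    mism <- charToRaw(cand) != obs
    sum(ifelse(mism, log_mis, log_match))
  }, numeric(1), USE.NAMES = FALSE)
  logprior <- log(candidates$count + params$prior_pseudocount)
  lp <- loglik + logprior
  if (all(!is.finite(lp))) return(rep(0, nrow(candidates)))
  w <- exp(lp - max(lp[is.finite(lp)]))
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Correct one observed barcode against the whitelist
#'
#' @inheritParams barcode_posterior
#' @param whitelist whitelist data.frame.
#' @return a `correction_result` list: `raw_barcode`, `corrected_barcode`
#'   (`NA` when uncorrected), `posterior` (`NA` when no candidates),
#'   `n_candidates`, `status` in `exact`/`corrected`/`ambiguous`/
#'   `no_candidate`. `exact` requires the observed barcode itself to be in
#'   the whitelist with posterior at or above the threshold; `corrected`
#'   requires the argmax candidate to reach the threshold; posterior ties go
#'   to the lexicographically smaller candidate.
#' @export
correct_barcode <- function(observed, quals, whitelist,
                            params = correction_params()) {
  cand <- candidates_within(observed, whitelist, params$max_hamming)
  if (nrow(cand) == 0) {
    return(structure(list(raw_barcode = observed, corrected_barcode = NA_character_,
                          posterior = NA_real_, n_candidates = 0L,
                          status = "no_candidate"),
                     class = "correction_result"))
  }
  post <- barcode_posterior(observed, quals, cand, params)
  obs_i <- which(cand$barcode == observed)
  if (length(obs_i) == 1 && post[obs_i] >= params$posterior_threshold) {
    return(structure(list(raw_barcode = observed, corrected_barcode = observed,
                          posterior = post[obs_i], n_candidates = nrow(cand),
                          status = "exact"),
                     class = "correction_result"))
  }
  best <- which(post == max(post))
  if (length(best) > 1) best <- best[order(cand$barcode[best])[1]]
  if (post[best] >= params$posterior_threshold) {
    status <- if (cand$barcode[best] == observed) "exact" else "corrected"
    return(structure(list(raw_barcode = observed,
                          corrected_barcode = cand$barcode[best],
                          posterior = post[best], n_candidates = nrow(cand),
                          status = status),
                     class = "correction_result"))
  }
  structure(list(raw_barcode = observed, corrected_barcode = NA_character_,
                 posterior = max(post), n_candidates = nrow(cand),
                 status = "ambiguous"),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result %s> %s -> %s (posterior %.4g, %d candidate%s)\n",
              x$status, x$raw_barcode,
              ifelse(is.na(x$corrected_barcode), "-", x$corrected_barcode),
              x$posterior, x$n_candidates,
              if (x$n_candidates == 1) "" else "s"))
  invisible(x)
}

#' Correct every row of a putative-barcode table
#'
#' @param table_in barcode table (data.frame or CSV path).
#' @param whitelist whitelist (data.frame or file path).
#' @param params a [correction_params()].
#' @param out_table optional CSV path for the corrected table.
#' @return list with `table` (input columns plus
#'   `corrected_barcode,posterior,status`) and `stats` (row counts per
#'   status, summing to the number of rows).
#' @export
correct_table <- function(table_in, whitelist, params = correction_params(),
                          out_table = NULL) {
  tab <- if (is.character(table_in)) read_barcode_table(table_in) else table_in
  need <- c("read_id", "barcode", "barcode_quals")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("barcode table missing column(s): ",
                         paste(miss, collapse = ", "))
  wl <- if (is.character(whitelist)) read_whitelist(whitelist) else whitelist
  n <- nrow(tab)
  corrected <- rep(NA_character_, n)
  posterior <- rep(NA_real_, n)
  status <- character(n)
  if (n > 0) {
    attr(wl, "bc_matrix") <- whitelist_matrix(wl)
    # candidate sets depend only on the raw barcode; cache per distinct barcode
    cand_cache <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      bc <- tab$barcode[i]
      cand <- get0(bc, envir = cand_cache, inherits = FALSE)
      if (is.null(cand)) {
        cand <- candidates_within(bc, wl, params$max_hamming)
        assign(bc, cand, envir = cand_cache)
      }
      if (nrow(cand) == 0) { status[i] <- "no_candidate"; next }
      post <- barcode_posterior(bc, tab$barcode_quals[i], cand, params)
      obs_i <- which(cand$barcode == bc)
      if (length(obs_i) == 1 && post[obs_i] >= params$posterior_threshold) {
        corrected[i] <- bc; posterior[i] <- post[obs_i]; status[i] <- "exact"
        next
      }
      best <- which(post == max(post))
      if (length(best) > 1) best <- best[order(cand$barcode[best])[1]]
      posterior[i] <- post[best]
      if (post[best] >= params$posterior_threshold) {
        corrected[i] <- cand$barcode[best]
        status[i] <- if (cand$barcode[best] == bc) "exact" else "corrected"
      } else {
        status[i] <- "ambiguous"
      }
    }
  }
  tab$corrected_barcode <- corrected
  tab$posterior <- posterior
  tab$status <- status
  stats <- list(n_rows = n,
                exact = sum(status == "exact"),
                corrected = sum(status == "corrected"),
                ambiguous = sum(status == "ambiguous"),
                no_candidate = sum(status == "no_candidate"))
  if (!is.null(out_table)) write_barcode_table(tab, out_table)
  list(table = tab, stats = stats)
}
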