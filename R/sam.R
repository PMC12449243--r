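# Lightweight SAM record layer. Alignments are held as a list with `header`
# (character vector of @-lines) and `records` (data.frame of the 11 mandatory
# fields plus a `tags` column holding the tab-joined optional fields).
# No installed R package can *write* records with arbitrary Z tags, so this
# layer is implemented here; Rsamtools converts to/from BAM when a `.bam`
# path is used, and serves as an independent reader in tests.

SAM_FIELDS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                "rnext", "pnext", "tlen", "seq", "qual")

#' Read a SAM (or BAM) file
#'
#' @param path `.sam` text file or `.bam` (converted via Rsamtools).
#' @return list of class `sam_set`: `header` (character vector) and
#'   `records` (data.frame with the 11 mandatory columns, `flag`/`pos`/
#'   `mapq` as integers, plus `tags` — the tab-joined optional fields, `""`
#'   when none).
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".sam")
    Rsamtools::asSam(path, sub("\\.sam$", "", tmp), overwrite = TRUE)
    path <- tmp
  }
  lines <- readLines(path)
  is_h <- startsWith(lines, "@")
  header <- lines[is_h]
  body <- lines[!is_h & nzchar(lines)]
  if (length(body) == 0) {
    rec <- data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), tags = character(0),
                      stringsAsFactors = FALSE)
    return(structure(list(header = header, records = rec), class = "sam_set"))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11)) {
    stop("malformed SAM record (fewer than 11 fields) at line ",
         which(!is_h & nzchar(lines))[which(nf < 11)[1]])
  }
  field <- function(k) vapply(parts, `[`, character(1), k)
  rec <- data.frame(qname = field(1), flag = as.integer(field(2)),
                    rname = field(3), pos = as.integer(field(4)),
                    mapq = as.integer(field(5)), cigar = field(6),
                    rnext = field(7), pnext = as.integer(field(8)),
                    tlen = as.integer(field(9)), seq = field(10),
                    qual = field(11),
                    tags = vapply(parts, function(p) {
                      if (length(p) > 11) paste(p[12:length(p)], collapse = "\t")
                      else ""
                    }, character(1)),
                    stringsAsFactors = FALSE)
  structure(list(header = header, records = rec), class = "sam_set")
}

#' Write a `sam_set` to SAM or BAM
#'
#' @param sam a `sam_set`.
#' @param path output `.sam` (text) or `.bam` (via Rsamtools conversion).
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path) {
  to_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  txt <- if (to_bam) tempfile(fileext = ".sam") else path
  rec <- sam$records
  body <- if (nrow(rec) == 0) character(0) else {
    base <- do.call(paste, c(rec[SAM_FIELDS], sep = "\t"))
    ifelse(nzchar(rec$tags), paste(base, rec$tags, sep = "\t"), base)
  }
  writeLines(c(sam$header, body), txt)
  if (to_bam) {
    Rsamtools::asBam(txt, sub("\\.bam$", "", path), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  invisible(path)
}

#' @export
print.sam_set <- function(x, ...) {
  cat(sprintf("<sam_set> %d header line%s, %d record%s\n",
              length(x$header), if (length(x$header) == 1) "" else "s",
              nrow(x$records), if (nrow(x$records) == 1) "" else "s"))
  invisible(x)
}

#' Get / set an optional SAM tag on tag strings
#'
#' `sam_get_tag` extracts the value of a two-character tag from the
#' tab-joined tag field; `sam_set_tag` sets (or replaces) a `Z`-type tag.
#'
#' @param tags character vector of tab-joined optional fields.
#' @param tag two-character tag name, e.g. `"CB"`.
#' @param value character vector of values (recycled), `NA` to leave a record
#'   untouched.
#' @return `sam_get_tag`: character vector of values (`NA` where absent);
#'   `sam_set_tag`: updated tag strings.
#' @export
sam_get_tag <- function(tags, tag) {
  pat <- paste0("(?:^|\t)", tag, ":[AZif]:([^\t]*)")
  m <- regmatches(tags, regexpr(pat, tags, perl = TRUE))
  out <- rep(NA_character_, length(tags))
  hit <- regexpr(pat, tags, perl = TRUE) != -1L
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' @rdname sam_get_tag
#' @export
sam_set_tag <- function(tags, tag, value) {
  value <- rep_len(value, length(tags))
  pat <- paste0("(^|\t)", tag, ":[AZif]:[^\t]*")
  stripped <- gsub(pat, "\\1", tags)
  stripped <- gsub("\t+", "\t", gsub("^\t|\t$", "", stripped))
  new <- ifelse(is.na(value), stripped,
                ifelse(nzchar(stripped),
                       paste0(stripped, "\t", tag, ":Z:", value),
                       paste0(tag, ":Z:", value)))
  new
}

# Flag helpers
flag_is_unmapped <- function(flag) bitwAnd(flag, 4L) != 0L
flag_is_reverse <- function(flag) bitwAnd(flag, 16L) != 0L
flag_is_secondary <- function(flag) bitwAnd(flag, 256L) != 0L
flag_is_supplementary <- function(flag) bitwAnd(flag, 2048L) != 0L
flag_is_primary <- function(flag) bitwAnd(flag, 2304L) == 0L  # !(secondary|supplementary)

# CIGAR arithmetic --------------------------------------------------------

cigar_ops <- function(cigar) {
  if (cigar == "*" || !nzchar(cigar)) {
    return(data.frame(len = integer(0), op = character(0)))
  }
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0 || sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

# Reference bases consumed by a CIGAR (M/D/N/=/X).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Leading / trailing soft-clip lengths.
cigar_clips <- function(cigar) {
  lead <- rep(0L, length(cigar))
  trail <- rep(0L, length(cigar))
  has_lead <- grepl("^\\d+S", cigar)
  has_trail <- grepl("[0-9]S$", cigar)
  lead[has_lead] <- as.integer(sub("^(\\d+)S.*$", "\\1", cigar[has_lead]))
  trail[has_trail] <- as.integer(sub("^.*?(\\d+)S$", "\\1", cigar[has_trail]))
  data.frame(lead = lead, trail = trail)
}

# Aligned reference blocks (M/D/=/X runs, split at N) as IRanges, 1-based.
cigar_ref_blocks <- function(cigar, pos) {
  ops <- cigar_ops(cigar)
  starts <- integer(0); ends <- integer(0)
  cur <- pos; bstart <- NA_integer_
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "D", "=", "X")) {
      if (is.na(bstart)) bstart <- cur
      cur <- cur + len
    } else if (op == "N") {
      if (!is.na(bstart)) { starts <- c(starts, bstart); ends <- c(ends, cur - 1L) }
      bstart <- NA_integer_
      cur <- cur + len
    }
    # I/S/H/P consume no reference
  }
  if (!is.na(bstart)) { starts <- c(starts, bstart); ends <- c(ends, cur - 1L) }
  IRanges::IRanges(start = starts, end = ends)
}

# Soft-clip-adjusted 5' position: start minus leading clip on the forward
# strand, alignment end plus trailing clip on the reverse strand. ONT indels
# shift raw positions; the clip adjustment keeps PCR duplicates keyed together.
fivep_position <- function(flag, pos, cigar) {
  clips <- cigar_clips(cigar)
  span <- cigar_ref_span(cigar)
  ifelse(flag_is_reverse(flag),
         pos + span - 1L + clips$trail,
         pos - clips$lead)
}
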