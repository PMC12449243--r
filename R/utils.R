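#' @keywords internal
"_PACKAGE"

# Phred+33 helpers. Qualities travel as ASCII strings (FASTQ convention) and
# are decoded to integer vectors only where arithmetic needs them.

#' Decode a Phred+33 quality string to integer qualities
#'
#' @param qual character scalar, Phred+33 encoded.
#' @return integer vector of per-base qualities in `[0, 93]`.
#' @export
phred_decode <- function(qual) {
  if (is.na(qual) || !nzchar(qual)) return(integer(0))
  as.integer(charToRaw(qual)) - 33L
}

#' Encode integer qualities as a Phred+33 string
#'
#' @param q integer vector of qualities in `[0, 93]`.
#' @return character scalar.
#' @export
phred_encode <- function(q) {
  if (length(q) == 0) return("")
  stopifnot(all(q >= 0L), all(q <= 93L))
  rawToChar(as.raw(as.integer(q) + 33L))
}

#' Per-base error probabilities from a quality string
#'
#' N bases are conventionally assigned quality 0 upstream, giving error
#' probability 1.
#' @param qual Phred+33 string.
#' @return numeric vector of `10^(-Q/10)`.
#' @export
phred_error_prob <- function(qual) 10^(-phred_decode(qual) / 10)

#' Reverse-complement a nucleotide string
#'
#' @param x character vector over `{A,C,G,T,N}` (case-insensitive).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse a character string (used for quality strings on the minus strand).
str_rev <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    rawToChar(rev(charToRaw(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Open path for line-writing, transparently gzipping on a .gz suffix.
open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}
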