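# 10X chemistry profiles. The read structure for droplet kits is
# adapter (read-1 primer) + cell barcode + UMI [+ poly-T] + cDNA; the 3' v3
# kit uses a 12 nt UMI, the 5' kit a 10 nt UMI and a TSO instead of poly-T
# (poly-T detection is simply absent there, which the parser tolerates).

#' Construct a chemistry profile describing the 10X read structure
#'
#' @param name profile name, e.g. `"10x-3p-v3"`.
#' @param adapter adapter sequence searched at the read start (the partial
#'   read-1 primer for 10X kits).
#' @param barcode_length cell-barcode length in nt (10X: 16).
#' @param umi_length UMI length in nt (12 for 3' v3, 10 for 5').
#' @param polyt_min_run minimum poly-T run length recorded after the UMI.
#' @param max_adapter_edit_distance maximum edit distance
#'   (substitutions + indels) tolerated for the adapter match.
#' @param search_window number of bases from each read end searched for the
#'   adapter; must cover adapter + barcode + UMI.
#' @return an object of class `chemistry_profile`.
#' @export
chemistry_profile <- function(name,
                              adapter,
                              barcode_length = 16L,
                              umi_length = 12L,
                              polyt_min_run = 10L,
                              max_adapter_edit_distance = 3L,
                              search_window = 100L) {
  stopifnot(barcode_length > 0L, umi_length > 0L,
            polyt_min_run > 0L, max_adapter_edit_distance >= 0L)
  if (search_window < nchar(adapter) + barcode_length + umi_length) {
    stop("search_window must cover adapter + barcode + UMI")
  }
  structure(
    list(name = name, adapter = toupper(adapter),
         barcode_length = as.integer(barcode_length),
         umi_length = as.integer(umi_length),
         polyt_min_run = as.integer(polyt_min_run),
         max_adapter_edit_distance = as.integer(max_adapter_edit_distance),
         search_window = as.integer(search_window)),
    class = "chemistry_profile")
}

#' Look up a built-in chemistry profile by name
#'
#' Known names: `"10x-3p-v3"` (16 nt barcode, 12 nt UMI, poly-T) and
#' `"10x-5p"` (16 nt barcode, 10 nt UMI). The adapter is the standard 10X
#' partial read-1 primer; both fields are plain data and can be overridden by
#' constructing a [chemistry_profile()] directly.
#'
#' @param name profile name.
#' @return a `chemistry_profile`.
#' @export
get_chemistry <- function(name) {
  r1_primer <- "CTACACGACGCTCTTCCGATCT"
  switch(name,
    "10x-3p-v3" = chemistry_profile("10x-3p-v3", r1_primer,
                                    barcode_length = 16L, umi_length = 12L),
    "10x-5p" = chemistry_profile("10x-5p", r1_primer,
                                 barcode_length = 16L, umi_length = 10L),
    stop("unknown chemistry profile: ", name))
}

#' @export
print.chemistry_profile <- function(x, ...) {
  cat(sprintf(
    "<chemistry_profile %s>\n  adapter: %s (max edit %d)\n  barcode %d nt, UMI %d nt, poly-T run >= %d\n  search window: %d nt\n",
    x$name, x$adapter, x$max_adapter_edit_distance,
    x$barcode_length, x$umi_length, x$polyt_min_run, x$search_window))
  invisible(x)
}
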