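#' Genomic interval utilities
#'
#' All coordinates inside natkit are 0-based half-open (`[start, end)`), the
#' BED convention. Conversion to and from 1-based inclusive GTF coordinates
#' happens only at the I/O boundary, so interval arithmetic never needs
#' off-by-one adjustments.
#'
#' @name intervals
#' @keywords internal
NULL

STRANDS <- c("+", "-", ".")

#' Construct a genomic interval
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A list of class `genome_interval`.
#' @export
genome_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start >= end)
    stop("invalid interval: require start < end, got [", start, ", ", end, ")")
  if (!strand %in% STRANDS)
    stop("strand must be one of ", paste(STRANDS, collapse = " "))
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genome_interval")
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d (%s)>\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

# ---- internal interval-set helpers -----------------------------------------
# Interval sets are data.frames with numeric columns start/end (0-based
# half-open), all on one chromosome/strand. IRanges does the arithmetic.

iv_df <- function(start, end) data.frame(start = as.numeric(start),
                                         end = as.numeric(end))

iv_to_ir <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(IRanges::IRanges())
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

ir_to_iv <- function(ir) {
  iv_df(BiocGenerics::start(ir) - 1L, BiocGenerics::end(ir))
}

#' Merge (reduce) an interval set into its minimal disjoint cover
#' @keywords internal
iv_merge <- function(df) {
  out <- ir_to_iv(IRanges::reduce(iv_to_ir(df)))
  out[order(out$start), , drop = FALSE]
}

#' Intersection of two interval sets
#' @keywords internal
iv_intersect <- function(a, b) {
  ir <- IRanges::intersect(iv_to_ir(a), iv_to_ir(b))
  ir_to_iv(ir)
}

#' Total overlap width (bp) between two interval sets
#' @keywords internal
iv_intersect_width <- function(a, b) {
  sum(BiocGenerics::width(IRanges::intersect(iv_to_ir(a), iv_to_ir(b))))
}

#' Set difference a \\ b of two interval sets
#' @keywords internal
iv_subtract <- function(a, b) {
  ir_to_iv(IRanges::setdiff(iv_to_ir(a), iv_to_ir(b)))
}

iv_total_width <- function(df) sum(df$end - df$start)

# ---- coordinate-string format ----------------------------------------------

#' Parse a coordinate string in transcription-direction notation
#'
#' Antisense gene coordinates are conventionally printed as
#' `chrom:from-to,strand` with `strand` coded `1`/`-1` and the two positions
#' given in the direction of transcription, so `from > to` on the minus
#' strand. The two printed integers are taken verbatim as the boundaries of a
#' half-open interval; the returned interval is normalised to `start < end`.
#' Both an en dash and a hyphen are accepted between the coordinates.
#'
#' @param text A string such as `"6:33422342-33405140,-1"`.
#' @return A [genome_interval].
#' @examples
#' parse_span_string("3:71630795-71678203,1")
#' @export
parse_span_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  m <- regmatches(txt,
    regexec("^([^:[:space:]]+):([0-9]+)[–-]([0-9]+),(-?1)$", txt))[[1]]
  if (length(m) != 5L)
    stop("cannot parse coordinate string: '", text,
         "' (expected chrom:start-end,1|-1)")
  a <- as.numeric(m[3]); b <- as.numeric(m[4])
  strand <- if (m[5] == "1") "+" else "-"
  genome_interval(m[2], min(a, b), max(a, b), strand)
}

#' Format a genomic interval in transcription-direction notation
#'
#' Inverse of [parse_span_string()]: on the plus strand the start is printed
#' first, on the minus strand the end is printed first.
#'
#' @param x A [genome_interval] (or anything with chrom/start/end/strand).
#' @return A string `chrom:from-to,1|-1`.
#' @export
format_span_string <- function(x) {
  if (identical(x$strand, "-"))
    sprintf("%s:%d-%d,-1", x$chrom, as.integer(x$end), as.integer(x$start))
  else
    sprintf("%s:%d-%d,1", x$chrom, as.integer(x$start), as.integer(x$end))
}
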