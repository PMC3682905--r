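#' @keywords internal
"_PACKAGE"

#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#'   coverage reduce
#' @importFrom IRanges IRanges Views viewSums
#' @importFrom S4Vectors queryHits subjectHits runValue runLength Rle mcols
NULL

# All user-facing tables use 0-based half-open coordinates (BED convention).
# IRanges/GRanges are 1-based closed; conversion is confined to these two
# helpers so no other code reasons about the offset.

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`; further columns become metadata columns.
#' @return a `GRanges` object in 1-based closed coordinates.
#' @keywords internal
as_granges0 <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[extra]
  gr
}

#' Convert GRanges back to a 0-based half-open table
#' @keywords internal
as_table0 <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(S4Vectors::mcols(gr)))
}

#' Round half away from zero
#'
#' Percentage rendering convention: 19.23 -> 19, 11.63 -> 12, 15.9 -> 16.
#' Base `round()` rounds half to even, which is not the convention used for
#' reported integer percentages.
#' @param x numeric
#' @return numeric rounded to the nearest integer, halves away from zero
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer percentage of a count over a total
#' @param k count
#' @param n total (must be > 0)
#' @return `round_half_up(100 * k / n)`
#' @export
percent_of <- function(k, n) {
  stopifnot(n > 0)
  round_half_up(100 * k / n)
}

#' Truncate a fraction to a one-decimal percentage
#'
#' Used for background proximity fractions (e.g. 1387/30321 -> 4.5).
#' @param frac fraction in [0, 1]
#' @return percentage truncated (not rounded) to one decimal place
#' @export
percent_trunc1 <- function(frac) floor(1000 * frac) / 10

# Derive a substream seed from a base seed and a fixed offset, staying within
# 32-bit integer range.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131 + offset) %% 2147483629)
}

check_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
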