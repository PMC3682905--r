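# Per-family aggregate flank metaprofiles and per-element heatmaps.

#' Aggregate flank coverage profile for one element family
#'
#' Agglomerates track coverage inside strand-oriented 50 bp bins over the
#' `span` bp flanking every element of a family, and normalizes to mean
#' per-base coverage per element per million retained reads:
#' \deqn{d(bin) = \frac{\sum_{elements} cov(bin)}{w \cdot n \cdot N/10^6}}
#' with \eqn{w} the bin width, \eqn{n} the element count and \eqn{N} the
#' track's retained library total. The returned 2*span/bin vector runs
#' 5' distal -> 5' boundary -> 3' boundary -> 3' distal, i.e. positions
#' along the genome in element orientation.
#'
#' @param track `coverage_track` (thresholded or not; see vignette)
#' @param elements full-length elements of one family
#' @param span flank width bp (default 6000)
#' @param bin_width bin width bp (default 50)
#' @return a `flank_profile`: list with `family`, `density` (numeric,
#'   length 2*span/bin_width), `bin_index` (signed: -1 is the 5' boundary
#'   bin, +1 the 3' boundary bin), `n_elements`, `library_total`
#' @export
aggregate_flank_profile <- function(track, elements, span = 6000L,
                                    bin_width = 50L) {
  stopifnot(inherits(track, "coverage_track"))
  if (!nrow(elements)) stop("n_elements = 0", call. = FALSE)
  if (track$library_total <= 0) stop("empty track library", call. = FALSE)
  mat <- flank_bin_matrix(track, elements, span, bin_width)
  fam <- if ("superfamily" %in% names(elements)) elements$superfamily[1]
         else NA_character_
  structure(
    list(family = fam,
         density = colMeans(mat),
         bin_index = as.integer(colnames(mat)),
         n_elements = nrow(elements),
         library_total = track$library_total),
    class = "flank_profile"
  )
}

#' Per-element flank heatmap matrix
#'
#' Same bin-density definition as [aggregate_flank_profile()] with
#' `n_elements = 1` per row; column means of the matrix equal the aggregate
#' profile exactly. Rows are ordered as the input elements and labelled by
#' element id.
#'
#' @inheritParams aggregate_flank_profile
#' @return a `flank_heatmap`: list with `family`, `matrix` (elements x
#'   2*span/bin_width densities), `bin_index`, `library_total`
#' @export
flank_heatmap <- function(track, elements, span = 6000L, bin_width = 50L) {
  stopifnot(inherits(track, "coverage_track"))
  if (!nrow(elements)) stop("n_elements = 0", call. = FALSE)
  mat <- flank_bin_matrix(track, elements, span, bin_width)
  fam <- if ("superfamily" %in% names(elements)) elements$superfamily[1]
         else NA_character_
  structure(
    list(family = fam, matrix = mat,
         bin_index = as.integer(colnames(mat)),
         library_total = track$library_total),
    class = "flank_heatmap"
  )
}

# elements x bins matrix of per-base mean coverage per million reads.
# Columns ordered 5' distal..boundary then 3' boundary..distal; signed
# column names -120..-1, 1..120 (for default geometry).
flank_bin_matrix <- function(track, elements, span, bin_width) {
  bins <- flank_bins(elements, span = span, bin_width = bin_width,
                     chrom_lengths = track$chrom_lengths)
  bins$sum <- coverage_sums(track, bins)
  n_bins <- span %/% bin_width
  scale <- bin_width * track$library_total / 1e6
  mat <- matrix(0, nrow = nrow(elements), ncol = 2L * n_bins,
                dimnames = list(elements$element_id,
                                c(-(n_bins:1), 1:n_bins)))
  col5 <- n_bins - bins$bin_index[bins$side == "5prime"]  # distal->boundary
  col3 <- n_bins + 1L + bins$bin_index[bins$side == "3prime"]
  row_of <- match(bins$element_id, elements$element_id)
  mat[cbind(row_of[bins$side == "5prime"], col5)] <-
    bins$sum[bins$side == "5prime"] / scale
  mat[cbind(row_of[bins$side == "3prime"], col3)] <-
    bins$sum[bins$side == "3prime"] / scale
  mat
}

#' Write a flank profile or heatmap as TSV
#' @param x `flank_profile` or `flank_heatmap`
#' @param path output file
#' @export
write_flank_tsv <- function(x, path) {
  if (inherits(x, "flank_profile")) {
    df <- data.frame(bin_index = x$bin_index, density = x$density)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (inherits(x, "flank_heatmap")) {
    df <- data.frame(element_id = rownames(x$matrix), x$matrix,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else stop("unsupported object", call. = FALSE)
  invisible(path)
}
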