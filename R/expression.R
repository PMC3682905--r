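# Expression quantification: per-region read counting, RPKM, the Poisson
# pairwise Z-score and fold change.
#
# Alignment tables: single-end reads are data.frames with `chrom`, `start`,
# `end`, `strand`, `mapq`; mate pairs additionally carry both mates (see
# sam-io.R). RNA-seq counting uses one row per fragment (pairs counted
# once); ChIP counting uses reads.

#' Count reads overlapping regions
#'
#' A read is counted once per region it overlaps by at least 1 bp; a read
#' spanning two regions increments both (documented multi-count, no
#' fractional assignment). Reads below `mapq_min` are excluded when
#' `unique_only` is set; the library total reported alongside is the number
#' of retained reads (overlapping a region or not).
#'
#' @param reads alignment data.frame (`chrom`, `start`, `end`, `mapq`)
#' @param regions region data.frame (`region_id`, `chrom`, `start`, `end`)
#' @param mapq_min minimum mapping quality (default 10, applied when
#'   `unique_only`)
#' @param unique_only drop reads with `mapq < mapq_min` (default TRUE)
#' @return list with `counts` (named integer vector, one per region) and
#'   `library_total`
#' @export
count_reads_in_regions <- function(reads, regions, mapq_min = 10,
                                   unique_only = TRUE) {
  check_cols(regions, c("region_id", "chrom", "start", "end"))
  if (!nrow(regions)) stop("regions must be non-empty", call. = FALSE)
  if (anyDuplicated(regions$region_id)) {
    stop("duplicate region ids", call. = FALSE)
  }
  if (unique_only && nrow(reads)) reads <- reads[reads$mapq >= mapq_min, ]
  counts <- stats::setNames(integer(nrow(regions)), regions$region_id)
  if (nrow(reads)) {
    hits <- GenomicRanges::findOverlaps(as_granges0(reads),
                                        as_granges0(regions),
                                        ignore.strand = TRUE)
    tab <- table(S4Vectors::subjectHits(hits))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  list(counts = counts, library_total = nrow(reads))
}

#' Count mate pairs overlapping regions (fragments counted once)
#'
#' RNA-seq counting unit: a pair is counted once per region that either
#' mate overlaps by >= 1 bp, never twice for one region. Uniqueness
#' requires both mates at or above `mapq_min`.
#'
#' @param pairs mate-pair data.frame
#' @param regions region data.frame (`region_id`, `chrom`, `start`, `end`)
#' @param mapq_min minimum mapQ for both mates (default 10)
#' @param unique_only drop non-unique pairs (default TRUE)
#' @return list with `counts` and `library_total` (retained pairs)
#' @export
count_pairs_in_regions <- function(pairs, regions, mapq_min = 10,
                                   unique_only = TRUE) {
  check_cols(regions, c("region_id", "chrom", "start", "end"))
  if (!nrow(regions)) stop("regions must be non-empty", call. = FALSE)
  if (anyDuplicated(regions$region_id)) {
    stop("duplicate region ids", call. = FALSE)
  }
  if (unique_only && nrow(pairs)) {
    pairs <- pairs[pairs$mapq1 >= mapq_min & pairs$mapq2 >= mapq_min, ]
  }
  counts <- stats::setNames(integer(nrow(regions)), regions$region_id)
  if (nrow(pairs)) {
    rg <- as_granges0(regions)
    h1 <- GenomicRanges::findOverlaps(
      as_granges0(data.frame(chrom = pairs$chrom, start = pairs$start1,
                             end = pairs$end1)), rg, ignore.strand = TRUE)
    h2 <- GenomicRanges::findOverlaps(
      as_granges0(data.frame(chrom = pairs$chrom, start = pairs$start2,
                             end = pairs$end2)), rg, ignore.strand = TRUE)
    key <- unique(c(paste(S4Vectors::queryHits(h1),
                          S4Vectors::subjectHits(h1)),
                    paste(S4Vectors::queryHits(h2),
                          S4Vectors::subjectHits(h2))))
    subj <- as.integer(sub("^.* ", "", key))
    tab <- table(subj)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  list(counts = counts, library_total = nrow(pairs))
}

#' Reads per kilobase per million mapped reads
#'
#' @param read_count reads (or fragments) in the region
#' @param length_bp region length in bp (> 0)
#' @param total_reads library size used for normalization (> 0)
#' @return RPKM = read_count / (length_bp/1000) / (total_reads/1e6)
#' @export
compute_rpkm <- function(read_count, length_bp, total_reads) {
  if (any(total_reads <= 0)) {
    stop("total_reads must be > 0 (undefined normalization)", call. = FALSE)
  }
  if (any(length_bp <= 0)) stop("length_bp must be > 0", call. = FALSE)
  read_count / (length_bp / 1000) / (total_reads / 1e6)
}

#' Aggregate per-element counts to repeat-family expression
#'
#' Family counts and lengths are sums over member elements; RPKM is computed
#' from the aggregates (not averaged over members).
#'
#' @param counts named vector of per-element read counts
#' @param lengths named vector of element lengths (bp), same names
#' @param family_map named character vector mapping element id -> family
#' @param library_total retained library size
#' @return data.frame: `region_id` (family), `read_count`, `length_bp`,
#'   `rpkm`
#' @export
family_expression <- function(counts, lengths, family_map, library_total) {
  ids <- names(counts)
  unmapped <- setdiff(ids, names(family_map))
  if (length(unmapped)) {
    stop("elements not mapped to a family: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  fam <- family_map[ids]
  cnt <- tapply(counts, fam, sum)
  len <- tapply(lengths[ids], fam, sum)
  data.frame(
    region_id = names(cnt),
    read_count = as.integer(cnt),
    length_bp = as.numeric(len),
    rpkm = compute_rpkm(as.numeric(cnt), as.numeric(len), library_total),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pairwise Poisson-model Z-score on RPKMs
#'
#' Deregulation score between two single libraries, treating each region's
#' RPKM as Poisson-distributed (variance ~ mean):
#' \deqn{z = (RPKM_A - RPKM_B) / \sqrt{RPKM_A + r_{AB} RPKM_B}}
#' with \eqn{r_{AB} = N_A / N_B} the ratio of aligned-read totals. Defined
#' as 0 when both RPKMs are 0. The statistic is well calibrated when RPKM is
#' on the scale of the raw count (1 kb regions, ~1e6 reads); see the
#' methods vignette for its behaviour elsewhere.
#'
#' @param rpkm_a,rpkm_b RPKM of the region in samples A and B
#' @param n_a,n_b total aligned reads in samples A and B
#' @return z-score (vectorized)
#' @export
poisson_zscore <- function(rpkm_a, rpkm_b, n_a, n_b) {
  if (any(rpkm_a < 0) || any(rpkm_b < 0)) {
    stop("RPKM must be non-negative", call. = FALSE)
  }
  if (any(n_a <= 0) || any(n_b <= 0)) {
    stop("library totals must be positive", call. = FALSE)
  }
  r_ab <- n_a / n_b
  denom <- sqrt(rpkm_a + r_ab * rpkm_b)
  z <- ifelse(denom == 0, 0, (rpkm_a - rpkm_b) / denom)
  as.numeric(z)
}

#' Pseudocounted expression fold change
#'
#' @param rpkm_test,rpkm_ref non-negative RPKMs
#' @param pseudocount added to both before the ratio (default 0.1; guards
#'   zero-reference regions)
#' @return (rpkm_test + pseudocount) / (rpkm_ref + pseudocount)
#' @export
fold_change <- function(rpkm_test, rpkm_ref, pseudocount = 0.1) {
  if (any(rpkm_test < 0) || any(rpkm_ref < 0)) {
    stop("RPKM must be non-negative", call. = FALSE)
  }
  if (pseudocount == 0 && any(rpkm_ref == 0)) {
    stop("pseudocount 0 with zero reference RPKM is undefined",
         call. = FALSE)
  }
  (rpkm_test + pseudocount) / (rpkm_ref + pseudocount)
}

#' Compare two samples region by region
#'
#' Convenience wrapper producing the standard comparison table (RPKMs,
#' Z-score, fold change) from two count sets over one region table.
#'
#' @param counts_a,counts_b outputs of [count_reads_in_regions()] for the
#'   same regions
#' @param regions region data.frame with `region_id` and lengths implied by
#'   `start`/`end` (or a `length_bp` column)
#' @param pseudocount for [fold_change()]
#' @return data.frame: `region_id`, `rpkm_a`, `rpkm_b`, `n_a`, `n_b`,
#'   `r_ab`, `z`, `fold_change`
#' @export
compare_samples <- function(counts_a, counts_b, regions, pseudocount = 0.1) {
  len <- if ("length_bp" %in% names(regions)) regions$length_bp else
    regions$end - regions$start
  rpkm_a <- compute_rpkm(as.numeric(counts_a$counts), len,
                         counts_a$library_total)
  rpkm_b <- compute_rpkm(as.numeric(counts_b$counts), len,
                         counts_b$library_total)
  data.frame(
    region_id = regions$region_id,
    rpkm_a = rpkm_a, rpkm_b = rpkm_b,
    n_a = counts_a$library_total, n_b = counts_b$library_total,
    r_ab = counts_a$library_total / counts_b$library_total,
    z = poisson_zscore(rpkm_a, rpkm_b, counts_a$library_total,
                       counts_b$library_total),
    fold_change = fold_change(rpkm_a, rpkm_b, pseudocount),
    stringsAsFactors = FALSE
  )
}

#' Per-element expression over full-length elements
#'
#' Counts reads passing the mapQ filter that overlap exactly one element
#' (reads touching two elements are discarded, keeping per-element signal
#' unambiguous), and computes RPKM per element.
#'
#' @param reads alignment data.frame
#' @param elements full-length element table
#'   (from [assemble_full_length_elements()])
#' @param mapq_min minimum mapQ (default 10)
#' @return data.frame: `region_id`, `read_count`, `length_bp`, `rpkm`
#' @export
per_element_expression <- function(reads, elements, mapq_min = 10) {
  if (nrow(reads)) reads <- reads[reads$mapq >= mapq_min, ]
  library_total <- nrow(reads)
  counts <- stats::setNames(integer(nrow(elements)), elements$element_id)
  if (nrow(reads) && nrow(elements)) {
    hits <- GenomicRanges::findOverlaps(as_granges0(reads),
                                        as_granges0(elements),
                                        ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    single <- names(which(table(q) == 1L))
    keep <- q %in% as.integer(single)
    tab <- table(S4Vectors::subjectHits(hits)[keep])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  data.frame(
    region_id = elements$element_id,
    read_count = as.integer(counts),
    length_bp = elements$end - elements$start,
    rpkm = if (library_total > 0) {
      compute_rpkm(as.numeric(counts), elements$end - elements$start,
                   library_total)
    } else rep(0, nrow(elements)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
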