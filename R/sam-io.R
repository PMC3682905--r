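# SAM and TSV alignment I/O.
#
# The simulators emit SAM text (mandatory fields only, SEQ/QUAL = "*") plus
# a TSV mirror of the same records; the readers accept either. SAM is read
# through Rsamtools (asBam + scanBam) so the records stay standards-clean.

sam_header <- function(chrom_lengths) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths)))
}

#' Write single-end alignments as SAM
#'
#' @param reads data.frame (`qname`, `chrom`, `start`, `end`, `strand`,
#'   `mapq`; 0-based half-open)
#' @param chrom_lengths named integer vector (for the header)
#' @param path output .sam file
#' @export
write_sam_reads <- function(reads, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sam_header(chrom_lengths), con)
  if (nrow(reads)) {
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    cigar <- sprintf("%dM", reads$end - reads$start)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                       reads$qname, flag, reads$chrom, reads$start + 1L,
                       as.integer(reads$mapq), cigar), con)
  }
  invisible(path)
}

#' Write mate pairs as SAM
#'
#' Two records per fragment with standard FR pair flags; TLEN carries the
#' signed outer fragment size.
#'
#' @param pairs mate-pair data.frame (see chimera.R for columns)
#' @param chrom_lengths named integer vector
#' @param path output .sam file
#' @export
write_sam_pairs <- function(pairs, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sam_header(chrom_lengths), con)
  if (nrow(pairs)) {
    f1 <- 1L + 2L + 64L + ifelse(pairs$strand1 == "-", 16L, 32L)
    f2 <- 1L + 2L + 128L + ifelse(pairs$strand2 == "-", 16L, 32L)
    cig1 <- sprintf("%dM", pairs$end1 - pairs$start1)
    cig2 <- sprintf("%dM", pairs$end2 - pairs$start2)
    tlen1 <- ifelse(pairs$start1 <= pairs$start2, pairs$fragment,
                    -pairs$fragment)
    l1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                  pairs$qname, f1, pairs$chrom, pairs$start1 + 1L,
                  as.integer(pairs$mapq1), cig1, pairs$start2 + 1L,
                  as.integer(tlen1))
    l2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                  pairs$qname, f2, pairs$chrom, pairs$start2 + 1L,
                  as.integer(pairs$mapq2), cig2, pairs$start1 + 1L,
                  as.integer(-tlen1))
    writeLines(as.vector(rbind(l1, l2)), con)
  }
  invisible(path)
}

sam_to_bam <- function(path) {
  bam <- tempfile(fileext = ".bam")
  Rsamtools::asBam(path, destination = sub("\\.bam$", "", bam),
                   overwrite = TRUE, indexDestination = FALSE)
}

#' Read single-end alignments from SAM
#'
#' @param path .sam file
#' @return alignment data.frame (`qname`, `chrom`, `start`, `end`,
#'   `strand`, `mapq`; 0-based half-open)
#' @export
read_sam_reads <- function(path) {
  bam <- sam_to_bam(path)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "qwidth", "strand", "mapq")
    )
  )[[1]]
  data.frame(
    qname = res$qname,
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + res$qwidth,
    strand = as.character(res$strand),
    mapq = as.integer(res$mapq),
    stringsAsFactors = FALSE
  )
}

#' Read mate pairs from SAM
#'
#' Records are joined on qname; the fragment size is recomputed as the
#' outer distance between the leftmost and rightmost aligned bases.
#'
#' @param path .sam file written by [write_sam_pairs()] (or any
#'   same-chromosome FR pairs)
#' @return mate-pair data.frame
#' @export
read_sam_pairs <- function(path) {
  bam <- sam_to_bam(path)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth", "strand", "mapq"),
      flag = Rsamtools::scanBamFlag(isPaired = TRUE)
    )
  )[[1]]
  df <- data.frame(
    qname = res$qname, flag = res$flag,
    chrom = as.character(res$rname),
    start = res$pos - 1L, end = res$pos - 1L + res$qwidth,
    strand = as.character(res$strand), mapq = as.integer(res$mapq),
    stringsAsFactors = FALSE
  )
  first <- df[bitwAnd(df$flag, 64L) != 0L, ]
  second <- df[bitwAnd(df$flag, 128L) != 0L, ]
  i <- match(first$qname, second$qname)
  ok <- !is.na(i)
  first <- first[ok, ]
  second <- second[i[ok], ]
  data.frame(
    qname = first$qname, chrom = first$chrom,
    start1 = first$start, end1 = first$end, strand1 = first$strand,
    mapq1 = first$mapq,
    start2 = second$start, end2 = second$end, strand2 = second$strand,
    mapq2 = second$mapq,
    fragment = pmax(first$end, second$end) - pmin(first$start,
                                                  second$start),
    stringsAsFactors = FALSE
  )
}

#' Write/read dependency-light TSV mirrors of alignment tables
#'
#' @param x alignment or mate-pair data.frame
#' @param path output .tsv
#' @export
write_alignment_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_tsv
#' @return the data.frame as written
#' @export
read_alignment_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
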