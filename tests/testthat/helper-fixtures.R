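# Shared fixture builders. Everything is generated in code; no binary data.

# a 6 kb MERVL provirus as three repeat rows: MT2 [0,500) + MERVL-int
# [500,5500) + MT2 [5500,6000), shiftable and reversible
mervl_triplet <- function(offset = 0L, chrom = "chr1", strand = "+") {
  data.frame(
    element_id = paste0("e", 1:3 + offset),
    family = c("MT2_Mm", "MERVL-int", "MT2_Mm"),
    erv_class = "III",
    part = c("LTR", "internal", "LTR"),
    chrom = chrom,
    start = offset + c(0L, 500L, 5500L),
    end = offset + c(500L, 5500L, 6000L),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

# single-end alignment rows
make_reads <- function(chrom, start, end, strand = "+", mapq = 60L) {
  n <- max(length(chrom), length(start), length(end))
  data.frame(
    qname = sprintf("r%03d", seq_len(n)),
    chrom = rep_len(chrom, n), start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n), strand = rep_len(strand, n),
    mapq = rep_len(as.integer(mapq), n),
    stringsAsFactors = FALSE
  )
}

# mate-pair rows with explicit fragment sizes
make_pairs <- function(chrom, start1, start2, fragment, read_len = 75L,
                       mapq = 60L) {
  n <- length(start1)
  data.frame(
    qname = sprintf("p%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    start1 = as.integer(start1), end1 = as.integer(start1 + read_len),
    strand1 = "+", mapq1 = rep_len(as.integer(mapq), n),
    start2 = as.integer(start2), end2 = as.integer(start2 + read_len),
    strand2 = "-", mapq2 = rep_len(as.integer(mapq), n),
    fragment = as.integer(fragment),
    stringsAsFactors = FALSE
  )
}

# two-gene models: gene A (+, exon1 [10000,10300), exon2 [11000,11400)),
# gene B (-, mirrored layout)
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), name = c("gA", "gB"),
    chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 31399L), transcript_length = c(700L, 700L),
    in_refseq = TRUE, in_ensembl = TRUE,
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB"),
    exon_index = c(1L, 2L, 1L, 2L),
    chrom = "chr1",
    start = c(10000L, 11000L, 31100L, 30000L),
    end = c(10300L, 11400L, 31400L, 30400L),
    strand = c("+", "+", "-", "-"),
    stringsAsFactors = FALSE
  )
  list(genes = genes, exons = exons)
}

# small fast simulation world for pipeline-level tests
fast_sim_config <- function(seed = 1L, ...) {
  base <- sim_config(seed)
  base$families$MERVL$n_full <- 4L
  base$families$MERVL$n_solo <- 6L
  base$families$IAPEz$n_full <- 3L
  base$families$IAPEz$n_solo <- 2L
  base$families$MMERVK10C$n_full <- 2L
  base$families$MMERVK10C$n_solo <- 2L
  base$genes$n <- 12L
  base$expression$gene_base_pairs <- 300
  base$chimeras <- list(n = 2L, support = c(8L, 12L),
                        ltr_offset = c(1500L, 2500L))
  base$stages$n_2c_specific <- 3L
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

# hypergeometric upper tail by explicit subset enumeration (oracle)
hyper_upper_enum <- function(k, K, N, n) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  if (n == 0) return(as.numeric(k <= 0))
  hits <- utils::combn(N, n, function(idx) sum(pop[idx]) >= k)
  mean(hits)
}
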