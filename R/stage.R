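# Two-cell-stage-specific gene classification and MT2-proximity enrichment.
#
# Stage tables are data.frames: `gene_id`, `rpm_oocyte`, `rpm_2c`, `rpm_8c`,
# `transcript_length`, plus derived `rpkm_*` columns.

#' Convert reads-per-million to RPKM
#'
#' @param rpm reads per million
#' @param transcript_length_bp transcript length in bp (> 0)
#' @return rpm / (transcript_length_bp / 1000)
#' @export
rpm_to_rpkm <- function(rpm, transcript_length_bp) {
  if (any(transcript_length_bp <= 0)) {
    stop("transcript length must be > 0", call. = FALSE)
  }
  rpm / (transcript_length_bp / 1000)
}

#' Attach stage RPKM columns to a stage table
#' @param table stage table with `rpm_*` and `transcript_length`
#' @return table with `rpkm_oocyte`, `rpkm_2c`, `rpkm_8c` added
#' @export
add_stage_rpkm <- function(table) {
  check_cols(table, c("gene_id", "rpm_oocyte", "rpm_2c", "rpm_8c",
                      "transcript_length"))
  for (st in c("oocyte", "2c", "8c")) {
    table[[paste0("rpkm_", st)]] <-
      rpm_to_rpkm(table[[paste0("rpm_", st)]], table$transcript_length)
  }
  table
}

#' Classify 2C-specific genes (oocyte < 2C > 8C)
#'
#' A gene is 2C-specific when its 2C-stage RPKM is at least `fold` times
#' both the oocyte and eight-cell RPKMs (inclusive thresholds) and clears a
#' minimal expression floor at the 2C stage (guards all-zero genes whose
#' tiny noise ratios would otherwise qualify).
#'
#' @param table stage table; `rpkm_*` columns are derived on the fly if
#'   absent
#' @param fold fold threshold (default 4)
#' @param min_rpkm_2c 2C-stage RPKM floor (default 0.5)
#' @return character vector of 2C-specific gene ids
#' @export
classify_2c_specific <- function(table, fold = 4, min_rpkm_2c = 0.5) {
  if (!all(c("rpkm_oocyte", "rpkm_2c", "rpkm_8c") %in% names(table))) {
    table <- add_stage_rpkm(table)
  }
  sel <- table$rpkm_2c >= fold * table$rpkm_oocyte &
    table$rpkm_2c >= fold * table$rpkm_8c &
    table$rpkm_2c >= min_rpkm_2c
  table$gene_id[sel]
}

#' Genes upregulated in a knockout line
#'
#' Pseudocounted fold change KO/wt at or above `fold` (inclusive).
#'
#' @param ko_rpkm,wt_rpkm named numeric vectors over the same gene universe
#' @param fold threshold (default 4)
#' @param pseudocount for [fold_change()] (default 0.1)
#' @return character vector of upregulated gene ids
#' @export
upregulated_genes <- function(ko_rpkm, wt_rpkm, fold = 4, pseudocount = 0.1) {
  if (is.null(names(ko_rpkm)) || is.null(names(wt_rpkm)) ||
      !setequal(names(ko_rpkm), names(wt_rpkm))) {
    stop("ko and wt must be named over the same gene universe",
         call. = FALSE)
  }
  wt_rpkm <- wt_rpkm[names(ko_rpkm)]
  fc <- fold_change(ko_rpkm, wt_rpkm, pseudocount)
  names(ko_rpkm)[fc >= fold]
}

#' Overlap of the 2C-specific set with KO-upregulated sets
#'
#' Venn-style counts: per-KO overlap with the 2C set, the union overlap
#' ("2C genes upregulated in one or more lines"), and the intersection
#' across all lines. Percentages are integer percentages of the 2C set
#' size.
#'
#' @param two_cell_set character vector of 2C-specific gene ids
#' @param upregulated_sets named list of character vectors, one per KO line
#' @return list with `per_set` (data.frame `set`, `overlap`, `percent`),
#'   `union_overlap`, `union_percent`, `all_lines_intersection`
#' @export
overlap_summary <- function(two_cell_set, upregulated_sets) {
  n2c <- length(two_cell_set)
  per_set <- data.frame(
    set = names(upregulated_sets),
    overlap = vapply(upregulated_sets,
                     function(s) length(intersect(two_cell_set, s)), 0L),
    stringsAsFactors = FALSE
  )
  per_set$percent <- if (n2c > 0) percent_of(per_set$overlap, n2c) else NA
  union_set <- intersect(two_cell_set,
                         Reduce(union, upregulated_sets, character()))
  inter_all <- if (length(upregulated_sets)) {
    intersect(two_cell_set, Reduce(intersect, upregulated_sets))
  } else character()
  list(
    per_set = per_set,
    union_overlap = length(union_set),
    union_percent = if (n2c > 0) percent_of(length(union_set), n2c) else NA,
    all_lines_intersection = sort(inter_all)
  )
}

#' MT2-LTR proximity enrichment of a gene set
#'
#' Counts genes whose TSS lies within (or at most `max_dist` bp from) an
#' LTR of the listed families, compares with the background fraction over
#' all genes, and reports a hypergeometric upper-tail p-value
#' P(X >= k) with population N = all genes, K = background-proximal genes
#' and n = |gene_set|.
#'
#' @param gene_set character vector of gene ids (subset of `all_genes`)
#' @param all_genes gene table (`gene_id`, `chrom`, `tss`)
#' @param elements repeat element table
#' @param families LTR families considered (default MT2/MT2A/MT2C)
#' @param max_dist inclusive distance threshold bp (default 5000)
#' @return list with `overlap_count`, `set_size`, `percentage` (integer, of
#'   the gene set), `background_count`, `background_total`,
#'   `background_fraction`, `background_percent_trunc1` (truncated to one
#'   decimal), `p_value`
#' @export
proximity_enrichment <- function(gene_set, all_genes, elements,
                                 families = c("MT2_Mm", "MT2A", "MT2C"),
                                 max_dist = 5000) {
  dist <- nearest_ltr_distance(all_genes, elements, ltr_families = families)
  proximal <- !is.na(dist) & dist <= max_dist
  K <- sum(proximal)
  N <- nrow(all_genes)
  in_set <- all_genes$gene_id %in% gene_set
  n <- sum(in_set)
  k <- sum(proximal & in_set)
  p <- if (n == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(
    overlap_count = k,
    set_size = n,
    percentage = if (n > 0) percent_of(k, n) else NA,
    background_count = K,
    background_total = N,
    background_fraction = K / N,
    background_percent_trunc1 = percent_trunc1(K / N),
    p_value = p
  )
}
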