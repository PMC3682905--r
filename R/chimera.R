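# Chimeric LTR-gene transcript detection from discordant mate pairs.
#
# Mate-pair tables carry one row per fragment: `qname`, `chrom`, `start1`,
# `end1`, `strand1`, `mapq1`, `start2`, `end2`, `strand2`, `mapq2`,
# `fragment` (outer distance in bp; both mates on one chromosome).

#' Estimate fragment-size statistics from concordant pairs
#'
#' Mean and SD of the outer fragment size, after two-sided quantile
#' trimming (default central 99%) so that genuinely discordant pairs do not
#' inflate the SD. The SD is corrected for the trimming-induced shrinkage
#' under the Normal fragment-size model (dividing by the theoretical
#' truncated-normal factor), so it is unbiased for well-behaved libraries.
#'
#' @param pairs mate-pair data.frame with a `fragment` column
#' @param trim fraction trimmed from each tail (default 0.005)
#' @param min_pairs minimum pairs required (default 50)
#' @return list(`mean`, `sd`, `n_pairs_used`)
#' @export
estimate_fragment_stats <- function(pairs, trim = 0.005, min_pairs = 50L) {
  frag <- pairs$fragment
  frag <- frag[is.finite(frag) & frag > 0]
  if (length(frag) < min_pairs) {
    stop(sprintf("need at least %d same-chromosome pairs, got %d",
                 min_pairs, length(frag)), call. = FALSE)
  }
  q <- stats::quantile(frag, c(trim, 1 - trim), names = FALSE, type = 7)
  used <- frag[frag >= q[1] & frag <= q[2]]
  m <- mean(used)
  # undo the variance shrinkage of central-(1-2*trim) normal truncation
  zt <- stats::qnorm(1 - trim)
  shrink <- 1 - 2 * zt * stats::dnorm(zt) / (1 - 2 * trim)
  s <- stats::sd(used) / sqrt(shrink)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate fragment-size distribution (sd must be > 0)",
         call. = FALSE)
  }
  list(mean = m, sd = s, n_pairs_used = length(used))
}

#' Detect chimeric LTR-gene transcript candidates
#'
#' A mate pair supports a chimera iff its fragment size deviates from the
#' mean by strictly more than one SD, one mate overlaps an ERV element lying
#' upstream (in gene orientation, within `max_upstream` bp) of the gene's
#' first exon -- or overlapping exon 1 itself -- and the other mate overlaps
#' an annotated exon of that same gene. Qualifying pairs are grouped by
#' (gene, ERV element). With `mode = "loose"`, the upstream requirement is
#' relaxed to "one mate in any listed ERV element, the other in any exon of
#' the gene" (the gene-level variant used for family breakdowns).
#'
#' @param pairs mate-pair data.frame
#' @param stats fragment statistics from [estimate_fragment_stats()]
#' @param erv_elements repeat element table (rows to consider as ERV side)
#' @param gene_models list with `genes` and `exons`
#'   (see [read_gene_models_gtf()])
#' @param max_upstream upstream search bound in bp (default 10000)
#' @param mode `"upstream"` (default) or `"loose"` (see above)
#' @param require_unique demand both mates mapQ >= `mapq_min` and distinct
#'   pair start coordinates (default TRUE)
#' @param mapq_min mapQ cutoff for `require_unique` (default 10)
#' @return data.frame of candidates: `gene_id`, `element_id`, `family`,
#'   `support`
#' @export
detect_chimeric_candidates <- function(pairs, stats, erv_elements,
                                       gene_models,
                                       max_upstream = 10000L,
                                       mode = c("upstream", "loose"),
                                       require_unique = TRUE,
                                       mapq_min = 10) {
  mode <- match.arg(mode)
  genes <- gene_models$genes
  exons <- gene_models$exons
  empty <- data.frame(gene_id = character(), element_id = character(),
                      family = character(), support = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs) || !nrow(erv_elements) || !nrow(genes)) return(empty)

  disc <- abs(pairs$fragment - stats$mean) > stats$sd
  if (require_unique) {
    disc <- disc & pairs$mapq1 >= mapq_min & pairs$mapq2 >= mapq_min
    key <- paste(pairs$chrom, pmin(pairs$start1, pairs$start2),
                 pmax(pairs$start1, pairs$start2))
    disc <- disc & !duplicated(key)
  }
  pairs <- pairs[disc, , drop = FALSE]
  if (!nrow(pairs)) return(empty)

  mate1 <- data.frame(chrom = pairs$chrom, start = pairs$start1,
                      end = pairs$end1)
  mate2 <- data.frame(chrom = pairs$chrom, start = pairs$start2,
                      end = pairs$end2)

  # eligible (gene, element) pairs under the chosen pairing rule
  links <- eligible_links(erv_elements, genes, exons, max_upstream, mode)
  if (!nrow(links)) return(empty)

  erv_gr <- as_granges0(erv_elements)
  ex_gr <- as_granges0(exons)
  hits <- function(mates, targets_gr) {
    GenomicRanges::findOverlaps(as_granges0(mates), targets_gr,
                                ignore.strand = TRUE)
  }
  support <- new.env(parent = emptyenv())
  per_query <- function(h, n) {
    out <- vector("list", n)
    sp <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    out[as.integer(names(sp))] <- sp
    out
  }
  n <- nrow(pairs)
  el1 <- per_query(hits(mate1, erv_gr), n)
  el2 <- per_query(hits(mate2, erv_gr), n)
  ex1 <- per_query(hits(mate1, ex_gr), n)
  ex2 <- per_query(hits(mate2, ex_gr), n)
  # either orientation: mate1 in ERV + mate2 in exon, or the reverse; a
  # single pair never counts twice for one (gene, element)
  for (i in seq_len(n)) {
    combos <- unique(rbind(
      link_combos(el1[[i]], ex2[[i]], erv_elements, exons),
      link_combos(el2[[i]], ex1[[i]], erv_elements, exons)
    ))
    if (is.null(combos) || !nrow(combos)) next
    ok <- paste(combos$gene_id, combos$element_id) %in%
      paste(links$gene_id, links$element_id)
    combos <- combos[ok, , drop = FALSE]
    for (j in seq_len(nrow(combos))) {
      k <- paste(combos$gene_id[j], combos$element_id[j], sep = "\r")
      support[[k]] <- (if (is.null(support[[k]])) 0L else support[[k]]) + 1L
    }
  }
  keys <- ls(support)
  if (!length(keys)) return(empty)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 1),
    element_id = vapply(parts, `[`, "", 2),
    stringsAsFactors = FALSE
  )
  out$family <- erv_elements$family[match(out$element_id,
                                          erv_elements$element_id)]
  out$support <- vapply(keys, function(k) support[[k]], 0L)
  out <- out[order(-out$support, out$gene_id), ]
  rownames(out) <- NULL
  out
}

link_combos <- function(els, exs, erv_elements, exons) {
  if (!length(els) || !length(exs)) return(NULL)
  expand.grid(gene_id = unique(exons$gene_id[exs]),
              element_id = erv_elements$element_id[els],
              stringsAsFactors = FALSE)
}

# (gene, element) pairs satisfying the positional pairing rule
eligible_links <- function(erv_elements, genes, exons, max_upstream, mode) {
  if (mode == "loose") {
    return(expand.grid(gene_id = genes$gene_id,
                       element_id = erv_elements$element_id,
                       stringsAsFactors = FALSE))
  }
  first <- exons[exons$exon_index == 1L, ]
  first <- first[match(genes$gene_id, first$gene_id), ]
  res <- lapply(seq_len(nrow(genes)), function(g) {
    fe <- first[g, ]
    if (is.na(fe$gene_id)) return(NULL)
    same <- erv_elements$chrom == fe$chrom
    if (genes$strand[g] == "+") {
      # upstream window ends at exon-1 start; overlap with exon 1 also allowed
      win_start <- fe$start - max_upstream
      ok <- same & erv_elements$end > win_start &
        erv_elements$start < fe$end
    } else {
      win_end <- fe$end + max_upstream
      ok <- same & erv_elements$start < win_end &
        erv_elements$end > fe$start
    }
    if (!any(ok)) return(NULL)
    data.frame(gene_id = genes$gene_id[g],
               element_id = erv_elements$element_id[ok],
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    return(data.frame(gene_id = character(), element_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Filter chimeric candidates and summarize by LTR family
#'
#' A transcript is scored valid when its chimeric mate-pair support exceeds
#' `min_support` (strictly: the default 5 admits support >= 6). The family
#' breakdown reports, per ERV family, the count of valid calls and its
#' integer percentage of all valid calls.
#'
#' @param candidates data.frame from [detect_chimeric_candidates()]
#' @param min_support strict support threshold (default 5)
#' @return list with `calls` (candidates plus `valid` flag) and `breakdown`
#'   (data.frame `family`, `count`, `percent`)
#' @export
filter_and_summarize <- function(candidates, min_support = 5L) {
  calls <- candidates
  calls$valid <- calls$support > min_support
  valid <- calls[calls$valid, , drop = FALSE]
  breakdown <- if (nrow(valid)) {
    tab <- sort(table(valid$family), decreasing = TRUE)
    data.frame(family = names(tab),
               count = as.integer(tab),
               percent = percent_of(as.integer(tab), nrow(valid)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(), count = integer(),
               percent = numeric(), stringsAsFactors = FALSE)
  }
  list(calls = calls, breakdown = breakdown)
}

#' Genes whose annotated first exon is an MT2-family LTR
#'
#' Returns genes present in both RefSeq and Ensembl whose first exon
#' overlaps an element of an MT2 family by at least 1 bp.
#'
#' @param gene_models list with `genes` and `exons`
#' @param erv_elements repeat element table
#' @param families family names counted as MT2 (default the `MT2*`
#'   annotations)
#' @return character vector of gene ids
#' @export
mt2_first_exon_genes <- function(gene_models, erv_elements,
                                 families = c("MT2_Mm", "MT2A", "MT2B",
                                              "MT2C")) {
  genes <- gene_models$genes
  exons <- gene_models$exons
  both <- genes$gene_id[genes$in_refseq & genes$in_ensembl]
  first <- exons[exons$exon_index == 1L & exons$gene_id %in% both, ]
  mt2 <- erv_elements[erv_elements$family %in% families, ]
  if (!nrow(first) || !nrow(mt2)) return(character())
  hits <- GenomicRanges::findOverlaps(as_granges0(first), as_granges0(mt2),
                                      ignore.strand = TRUE)
  sort(unique(first$gene_id[S4Vectors::queryHits(hits)]))
}
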