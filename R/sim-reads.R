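# Synthetic alignments: paired-end RNA-seq (with planted chimeric
# fragments) and single-end ChIP reads (spreading vs focal flank
# enrichment).

#' Simulate paired-end RNA-seq alignments
#'
#' Per-region fragment counts are Poisson around the expected value
#' (config expression base x the sample's family/gene fold factor), or
#' exact when `noise = "none"`. Fragments are Normal(mean, sd), mates
#' `read_len` bp. Planted chimeras are emitted as pairs with one mate in
#' the planted LTR and the other in the gene's second exon; their fragment
#' sizes (the LTR-to-exon genomic distance) exceed mean + sd by
#' construction. The configured unique fraction gets mapQ 60, the rest 0.
#'
#' @param genome output of [generate_toy_genome()]
#' @param sample sample name; must appear in `config$expression$folds`
#' @param config a [sim_config()]; defaults to the genome's own
#' @return mate-pair data.frame; attribute `planted_counts` holds the
#'   realized per-region fragment counts
#' @export
simulate_rnaseq_pairs <- function(genome, sample,
                                  config = genome$config) {
  ex <- config$expression
  folds <- ex$folds[[sample]]
  if (is.null(folds)) stop("no fold factors for sample ", sample,
                           call. = FALSE)
  set.seed(substream_seed(config$seed,
                          17L + sum(utf8ToInt(sample))))
  fr <- config$fragments
  rl <- fr$read_len

  regions <- rbind(
    data.frame(region_id = genome$full_length$element_id,
               chrom = genome$full_length$chrom,
               start = genome$full_length$start,
               end = genome$full_length$end,
               expected = ex$element_base_pairs *
                 folds[genome$full_length$superfamily],
               stringsAsFactors = FALSE),
    data.frame(region_id = genome$gene_models$genes$gene_id,
               chrom = genome$gene_models$genes$chrom,
               start = vapply(split(genome$gene_models$exons$start,
                                    genome$gene_models$exons$gene_id), min,
                              0L)[genome$gene_models$genes$gene_id],
               end = vapply(split(genome$gene_models$exons$end,
                                  genome$gene_models$exons$gene_id), max,
                            0L)[genome$gene_models$genes$gene_id],
               expected = ex$gene_base_pairs * folds[["gene"]],
               stringsAsFactors = FALSE)
  )
  counts <- if (identical(ex$noise, "none")) {
    as.integer(round(regions$expected))
  } else {
    stats::rpois(nrow(regions), regions$expected)
  }
  total <- sum(counts)
  out <- NULL
  if (total > 0) {
    idx <- rep.int(seq_len(nrow(regions)), counts)
    frag <- pmax(round(stats::rnorm(total, fr$mean, fr$sd)), 2L * rl)
    width <- regions$end[idx] - regions$start[idx]
    frag <- pmin(frag, width)  # fragments fit inside their region
    s1 <- regions$start[idx] +
      floor(stats::runif(total) * (width - frag + 1))
    s2 <- s1 + frag - rl
    mapq <- ifelse(stats::runif(total) < ex$unique_fraction, 60L, 0L)
    out <- data.frame(
      qname = sprintf("%s_frag%06d", sample, seq_len(total)),
      chrom = regions$chrom[idx],
      start1 = as.integer(s1), end1 = as.integer(s1 + rl),
      strand1 = "+", mapq1 = mapq,
      start2 = as.integer(s2), end2 = as.integer(s2 + rl),
      strand2 = "-", mapq2 = mapq,
      fragment = as.integer(frag),
      stringsAsFactors = FALSE
    )
  }

  # planted chimeric fragments: mate1 in the LTR, mate2 in exon 2
  chim <- genome$truth$chimeras
  if (nrow(chim)) {
    reps <- genome$repeats
    exons <- genome$gene_models$exons
    chim_rows <- lapply(seq_len(nrow(chim)), function(i) {
      el <- reps[reps$element_id == chim$element_id[i], ]
      e2 <- exons[exons$gene_id == chim$gene_id[i] &
                    exons$exon_index == 2L, ]
      if (!nrow(e2)) e2 <- exons[exons$gene_id == chim$gene_id[i], ][1, ]
      n <- chim$support[i]
      # distinct start coordinates so unique-pair dedup keeps all of them
      s1 <- el$start + sample.int(max(el$end - el$start - rl, n), n)
      s2 <- e2$start + ((seq_len(n) - 1L) %% max(e2$end - e2$start - rl, 1L))
      data.frame(
        qname = sprintf("%s_chim%s_%02d", sample, chim$gene_id[i],
                        seq_len(n)),
        chrom = el$chrom,
        start1 = as.integer(pmin(s1, el$end - rl)),
        end1 = as.integer(pmin(s1, el$end - rl) + rl),
        strand1 = "+", mapq1 = 60L,
        start2 = as.integer(s2), end2 = as.integer(s2 + rl),
        strand2 = "-", mapq2 = 60L,
        fragment = 0L,
        stringsAsFactors = FALSE
      )
    })
    chim_df <- do.call(rbind, chim_rows)
    chim_df$fragment <- as.integer(
      pmax(chim_df$end1, chim_df$end2) - pmin(chim_df$start1,
                                              chim_df$start2))
    out <- rbind(out, chim_df)
  }
  if (is.null(out)) {
    out <- data.frame(qname = character(), chrom = character(),
                      start1 = integer(), end1 = integer(),
                      strand1 = character(), mapq1 = integer(),
                      start2 = integer(), end2 = integer(),
                      strand2 = character(), mapq2 = integer(),
                      fragment = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "planted_counts") <- stats::setNames(counts, regions$region_id)
  out
}

#' Simulate single-end ChIP alignments
#'
#' Uniform background at `background_rate` reads/bp genome-wide, plus
#' family-specific enrichment over full-length elements (the default
#' background rate keeps per-position read collisions rare, so duplicate
#' collapsing in [build_coverage()] does not saturate the planted
#' enrichment): body reads at
#' `enrichment` x background for every profiled family; for "spreading"
#' families additional flank reads decay exponentially with the configured
#' half-length (rate continuous at the boundary: enrichment x background at
#' distance 0); "focal" families get no flank signal. Read counts are
#' Poisson; positions uniform (body/background) or inverse-CDF samples of
#' the truncated exponential (flanks); strands random; mapQ 60.
#'
#' @param genome output of [generate_toy_genome()]
#' @param antibody label stored in qnames (also varies the random
#'   substream)
#' @param config a [sim_config()]; defaults to the genome's own
#' @param flank_span flank width receiving decay reads (default 6000)
#' @return alignment data.frame (`qname`, `chrom`, `start`, `end`,
#'   `strand`, `mapq`)
#' @export
simulate_chip_reads <- function(genome, antibody = "chip",
                                config = genome$config,
                                flank_span = 6000L) {
  cp <- config$chip
  set.seed(substream_seed(config$seed, 29L + sum(utf8ToInt(antibody))))
  rl <- cp$read_len
  beta <- cp$background_rate
  pieces <- list()
  add <- function(chrom, pos, strand = NULL) {
    if (!length(pos)) return()
    if (is.null(strand)) {
      strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    }
    pieces[[length(pieces) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(pos), strand = strand,
      stringsAsFactors = FALSE)
  }
  # background
  for (ch in names(config$genome)) {
    len <- config$genome[[ch]]
    n <- stats::rpois(1L, beta * len)
    add(ch, floor(stats::runif(n) * (len - rl)))
  }
  # element signal
  fl <- genome$full_length
  for (i in seq_len(nrow(fl))) {
    prof <- cp$profiles[[fl$superfamily[i]]]
    if (is.null(prof)) next
    body_len <- fl$end[i] - fl$start[i]
    n_body <- stats::rpois(1L, (prof$enrichment - 1) * beta * body_len)
    add(fl$chrom[i],
        fl$start[i] + floor(stats::runif(n_body) * (body_len - rl)))
    if (identical(prof$mode, "spreading") && prof$half_length > 0) {
      h <- prof$half_length
      S <- flank_span
      expct <- (prof$enrichment - 1) * beta * (h / log(2)) *
        (1 - 2^(-S / h))
      for (side in c(-1L, 1L)) {
        n_f <- stats::rpois(1L, expct)
        u <- stats::runif(n_f)
        d <- floor(-h * log2(1 - u * (1 - 2^(-S / h))))
        strand <- sample(c("+", "-"), n_f, replace = TRUE)
        # read 5' end sits exactly at the sampled decay distance
        five <- if (side < 0) fl$start[i] - 1L - d else fl$end[i] + d
        pos <- ifelse(strand == "-", five - rl + 1L, five)
        len <- config$genome[[fl$chrom[i]]]
        pos <- pmin(pmax(pos, 0), len - rl)
        add(fl$chrom[i], pos, strand)
      }
    }
  }
  if (!length(pieces)) {
    return(data.frame(qname = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), mapq = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, pieces)
  n <- nrow(df)
  data.frame(
    qname = sprintf("%s_read%07d", antibody, seq_len(n)),
    chrom = df$chrom, start = df$start, end = df$start + rl,
    strand = df$strand,
    mapq = 60L,
    stringsAsFactors = FALSE
  )
}

#' Simulate a blastomere stage-expression table
#'
#' Planted 2C-specific genes are expressed at `fold` x the oocyte/8C level
#' at the 2C stage (default 8, i.e. 2x the classification threshold);
#' all other genes are flat across stages. Multiplicative lognormal noise
#' with sigma `noise_sigma` (0 = exact). Emitted as RPM with the gene's
#' transcript length, the native format of the classifier input.
#'
#' @param genome output of [generate_toy_genome()]
#' @param config a [sim_config()]; defaults to the genome's own
#' @return stage table data.frame (`gene_id`, `rpm_oocyte`, `rpm_2c`,
#'   `rpm_8c`, `transcript_length`)
#' @export
simulate_stage_table <- function(genome, config = genome$config) {
  st <- config$stages
  set.seed(substream_seed(config$seed, 43L))
  genes <- genome$gene_models$genes
  is2c <- genes$gene_id %in% genome$truth$twoc_genes
  noise <- function(n) {
    if (st$noise_sigma > 0) exp(stats::rnorm(n, 0, st$noise_sigma))
    else rep(1, n)
  }
  n <- nrow(genes)
  rpkm_oo <- st$base_rpkm * noise(n)
  rpkm_8c <- st$base_rpkm * noise(n)
  rpkm_2c <- st$base_rpkm * ifelse(is2c, st$fold, 1) * noise(n)
  data.frame(
    gene_id = genes$gene_id,
    rpm_oocyte = rpkm_oo * genes$transcript_length / 1000,
    rpm_2c = rpkm_2c * genes$transcript_length / 1000,
    rpm_8c = rpkm_8c * genes$transcript_length / 1000,
    transcript_length = genes$transcript_length,
    stringsAsFactors = FALSE
  )
}
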