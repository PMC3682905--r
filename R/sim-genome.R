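# Synthetic toy genome: full-length proviruses, solo LTRs and gene models
# with configurable MT2 proximity, plus the ground truth needed for
# parameter-recovery tests.

#' Simulation configuration
#'
#' Returns the default stated world for the synthetic data generators;
#' override any component by name. Defaults: a 3 x 400 kb toy genome; 12
#' full-length MERVL, 8 IAPEz and 6 MMERVK10C proviruses (LTR-internal-LTR
#' with identical LTR annotations) spaced so that 6 kb flanks stay free of
#' other elements; 20/6/4 solo LTRs; 40 three-exon genes of which a 0.15
#' fraction get a TSS within 5 kb of an MT2 LTR; RNA-seq fragments
#' Normal(200, 30) with 75 bp mates and Poisson region counts; ChIP
#' enrichment 50x spreading with 500 bp decay half-length at IAPEz, focal
#' (body-only) 8x at MERVL, 15x spreading with 300 bp half-length at
#' MMERVK10C over a 0.004 reads/bp background; 6 planted LTR-gene chimeras;
#' 8 planted 2C-specific genes at 8-fold over oocyte/8C with lognormal
#' noise sigma 0.2.
#'
#' @param seed integer seed; all generator randomness derives from it
#' @param ... named overrides of top-level components
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = c(chr1 = 400000L, chr2 = 400000L, chr3 = 400000L),
    families = list(
      MERVL = list(ltr_family = "MT2_Mm", internal_family = "MERVL-int",
                   ltr_len = 500L, internal_len = 5000L,
                   n_full = 12L, n_solo = 20L),
      IAPEz = list(ltr_family = "IAPLTR1_Mm", internal_family = "IAPEz-int",
                   ltr_len = 350L, internal_len = 6300L,
                   n_full = 8L, n_solo = 6L),
      MMERVK10C = list(ltr_family = "RLTR10C",
                       internal_family = "MMERVK10C-int",
                       ltr_len = 500L, internal_len = 5500L,
                       n_full = 6L, n_solo = 4L)
    ),
    genes = list(n = 40L, exon_lengths = c(300L, 400L, 500L),
                 intron_lengths = c(800L, 1200L),
                 frac_near_mt2 = 0.15, near_mt2_max_dist = 5000L),
    expression = list(
      element_base_pairs = 20,     # expected RNA-seq pairs per provirus
      gene_base_pairs = 2500,      # expected pairs per gene
      unique_fraction = 0.95,      # fraction of pairs with mapQ >= 10
      folds = list(wt = c(MERVL = 1, IAPEz = 1, MMERVK10C = 1, gene = 1),
                   ko = c(MERVL = 27, IAPEz = 4, MMERVK10C = 1, gene = 1)),
      noise = "poisson"            # or "none" for exact planted counts
    ),
    fragments = list(mean = 200, sd = 30, read_len = 75L),
    chip = list(
      background_rate = 0.004,    # reads/bp; keeps duplicate collisions rare
      read_len = 36L,
      profiles = list(
        IAPEz = list(mode = "spreading", enrichment = 50,
                     half_length = 500),
        MERVL = list(mode = "focal", enrichment = 8, half_length = 0),
        MMERVK10C = list(mode = "spreading", enrichment = 15,
                         half_length = 300)
      )
    ),
    chimeras = list(n = 6L, support = c(8L, 12L, 6L, 9L, 7L, 10L),
                    ltr_offset = c(1500L, 2500L)),
    stages = list(n_2c_specific = 8L, fold = 8, base_rpkm = 1,
                  noise_sigma = 0.2)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "sim_config"
  cfg
}

# non-overlapping placement with bounded retries; `occupied` is a
# data.frame(chrom,start,end); returns chosen (chrom,start)
place_interval <- function(size, pad, genome, occupied, what,
                           max_try = 200L) {
  for (i in seq_len(max_try)) {
    ch <- sample(names(genome), 1L)
    max_start <- genome[[ch]] - size - pad
    if (max_start <= pad) next
    s <- sample.int(max_start - pad, 1L) + pad
    clash <- any(occupied$chrom == ch &
                   occupied$start < s + size + pad &
                   occupied$end > s - pad)
    if (!clash) return(list(chrom = ch, start = s))
  }
  stop(sprintf("infeasible placement after %d retries: %s (size %d, pad %d)",
               max_try, what, size, pad), call. = FALSE)
}

#' Generate the toy genome: repeats, genes and ground truth
#'
#' Places full-length LTR-internal-LTR proviruses (identical LTR family,
#' zero inter-component gaps) with enough spacing that each element's 6 kb
#' flanks contain no other repeat, solo LTRs, and gene models. The
#' configured fraction of genes receive a dedicated solo MT2 LTR within
#' 5 kb upstream of their TSS; chimera genes additionally get an MT2 LTR
#' 1.5-2.5 kb upstream of exon 1.
#'
#' @param config a [sim_config()]
#' @return list with `repeats` (element table), `gene_models`
#'   (genes + exons), `full_length` (assembled-truth table), `truth`
#'   (planted chimera table, 2C gene ids, per-region expected expression
#'   scaffold) and `config`
#' @export
generate_toy_genome <- function(config) {
  set.seed(substream_seed(config$seed, 11L))
  genome <- config$genome
  occupied <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  rep_rows <- list()
  fl_rows <- list()
  eid <- 0L
  next_id <- function(fam) {
    eid <<- eid + 1L
    sprintf("%s_%d", fam, eid)
  }
  add_rep <- function(fam, part, cls, ch, s, e, strand) {
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      element_id = next_id(fam), family = fam, erv_class = cls,
      part = part, chrom = ch, start = s, end = e, strand = strand,
      stringsAsFactors = FALSE)
  }
  part_tab <- default_part_table()
  cls_of <- function(fam) infer_class(fam, part_tab)

  # full-length proviruses, padded by a full flank span plus margin so
  # metaprofiles see clean background
  for (sf in names(config$families)) {
    fc <- config$families[[sf]]
    span <- 2L * fc$ltr_len + fc$internal_len
    for (i in seq_len(fc$n_full)) {
      pos <- place_interval(span, 6500L, genome, occupied,
                            paste("full-length", sf))
      strand <- sample(c("+", "-"), 1L)
      s <- pos$start
      add_rep(fc$ltr_family, "LTR", cls_of(fc$ltr_family),
              pos$chrom, s, s + fc$ltr_len, strand)
      add_rep(fc$internal_family, "internal", cls_of(fc$internal_family),
              pos$chrom, s + fc$ltr_len, s + fc$ltr_len + fc$internal_len,
              strand)
      add_rep(fc$ltr_family, "LTR", cls_of(fc$ltr_family),
              pos$chrom, s + fc$ltr_len + fc$internal_len, s + span, strand)
      fl_rows[[length(fl_rows) + 1L]] <- data.frame(
        element_id = sprintf("%s_FL_%s_%d", sf, pos$chrom, s),
        superfamily = sf, chrom = pos$chrom, start = s, end = s + span,
        strand = strand, stringsAsFactors = FALSE)
      occupied <- rbind(occupied,
                        data.frame(chrom = pos$chrom, start = s - 6000L,
                                   end = s + span + 6000L))
    }
  }
  # solo LTRs
  for (sf in names(config$families)) {
    fc <- config$families[[sf]]
    for (i in seq_len(fc$n_solo)) {
      pos <- place_interval(fc$ltr_len, 500L, genome, occupied,
                            paste("solo LTR", sf))
      strand <- sample(c("+", "-"), 1L)
      add_rep(fc$ltr_family, "LTR", cls_of(fc$ltr_family),
              pos$chrom, pos$start, pos$start + fc$ltr_len, strand)
      occupied <- rbind(occupied,
                        data.frame(chrom = pos$chrom, start = pos$start,
                                   end = pos$start + fc$ltr_len))
    }
  }

  # genes: exon layout in transcript orientation
  gc <- config$genes
  gene_span <- sum(gc$exon_lengths) + sum(gc$intron_lengths)
  n_genes <- gc$n
  n_chim <- config$chimeras$n
  n_near <- max(round(gc$frac_near_mt2 * n_genes) - n_chim, 0L)
  genes <- list()
  exons <- list()
  mervl_ltr_len <- config$families$MERVL$ltr_len
  chim_gene_idx <- seq_len(n_chim)
  near_gene_idx <- seq(n_chim + 1L, length.out = n_near)
  chim_elements <- character(n_chim)
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%02d", g)
    # genes that carry a planted upstream MT2 LTR are placed together with
    # it as one block, guaranteeing the required TSS-LTR distance
    ltr_gap <- if (g %in% chim_gene_idx) {
      sample(seq(config$chimeras$ltr_offset[1],
                 config$chimeras$ltr_offset[2]), 1L)
    } else if (g %in% near_gene_idx) {
      sample.int(gc$near_mt2_max_dist - mervl_ltr_len, 1L)
    } else NA_integer_
    block <- if (is.na(ltr_gap)) gene_span else
      gene_span + ltr_gap + mervl_ltr_len
    pos <- place_interval(block, 1000L, genome, occupied,
                          paste("gene", gid))
    strand <- sample(c("+", "-"), 1L)
    if (!is.na(ltr_gap)) {
      # transcript direction runs from the LTR into the gene
      if (strand == "+") {
        ltr_start <- pos$start
        pos$start <- pos$start + mervl_ltr_len + ltr_gap
      } else {
        ltr_start <- pos$start + gene_span + ltr_gap
      }
      add_rep("MT2_Mm", "LTR", "III", pos$chrom, ltr_start,
              ltr_start + mervl_ltr_len, strand)
      if (g %in% chim_gene_idx) {
        chim_elements[g] <- rep_rows[[length(rep_rows)]]$element_id
      }
      occupied <- rbind(occupied,
                        data.frame(chrom = pos$chrom, start = ltr_start,
                                   end = ltr_start + mervl_ltr_len))
    }
    offs <- cumsum(c(0L, utils::head(as.vector(rbind(gc$exon_lengths,
                                              c(gc$intron_lengths, 0L))),
                              -1L)))
    ex_starts_tx <- offs[seq(1L, by = 2L, length.out =
                               length(gc$exon_lengths))]
    if (strand == "+") {
      es <- pos$start + ex_starts_tx
      ee <- es + gc$exon_lengths
      idx <- seq_along(es)
    } else {
      ee <- pos$start + gene_span - ex_starts_tx
      es <- ee - gc$exon_lengths
      idx <- seq_along(es)
    }
    exons[[g]] <- data.frame(gene_id = gid, exon_index = idx,
                             chrom = pos$chrom, start = es, end = ee,
                             strand = strand, stringsAsFactors = FALSE)
    tss <- if (strand == "+") pos$start else pos$start + gene_span - 1L
    genes[[g]] <- data.frame(
      gene_id = gid, name = gid, chrom = pos$chrom, strand = strand,
      tss = tss, transcript_length = sum(gc$exon_lengths),
      in_refseq = TRUE, in_ensembl = TRUE, stringsAsFactors = FALSE)
    occupied <- rbind(occupied,
                      data.frame(chrom = pos$chrom, start = pos$start,
                                 end = pos$start + gene_span))
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)

  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    empty_repeats()
  repeats <- repeats[order(repeats$chrom, repeats$start), ]
  rownames(repeats) <- NULL
  full_length <- if (length(fl_rows)) do.call(rbind, fl_rows) else
    data.frame(element_id = character(), superfamily = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  full_length <- full_length[order(full_length$chrom, full_length$start), ]
  rownames(full_length) <- NULL

  chimeras <- data.frame(
    gene_id = genes$gene_id[chim_gene_idx],
    element_id = chim_elements,
    support = config$chimeras$support[seq_len(n_chim)],
    stringsAsFactors = FALSE)
  twoc <- genes$gene_id[sample.int(n_genes, config$stages$n_2c_specific)]

  list(
    repeats = repeats,
    gene_models = list(genes = genes, exons = exons),
    full_length = full_length,
    truth = list(
      chimeras = chimeras,
      twoc_genes = sort(twoc),
      near_mt2_genes = genes$gene_id[c(chim_gene_idx, near_gene_idx)]
    ),
    config = config
  )
}
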