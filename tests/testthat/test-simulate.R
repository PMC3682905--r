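test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- fast_sim_config(421)
  g1 <- generate_toy_genome(cfg)
  g2 <- generate_toy_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(simulate_rnaseq_pairs(g1, "wt"),
                   simulate_rnaseq_pairs(g2, "wt"))
  expect_identical(simulate_chip_reads(g1), simulate_chip_reads(g2))
  expect_identical(simulate_stage_table(g1), simulate_stage_table(g2))
  # a different seed moves the world
  expect_false(identical(generate_toy_genome(fast_sim_config(422))$repeats,
                         g1$repeats))
})

test_that("assembly recovers exactly the planted full-length elements", {
  cfg <- fast_sim_config(77)
  g <- generate_toy_genome(cfg)
  fl <- assemble_full_length_elements(g$repeats)
  expect_equal(nrow(fl), nrow(g$full_length))
  expect_equal(fl[c("chrom", "start", "end", "strand", "superfamily")],
               g$full_length[c("chrom", "start", "end", "strand",
                               "superfamily")],
               ignore_attr = TRUE)
  # configured copy numbers respected
  expect_equal(sum(fl$superfamily == "MERVL"),
               cfg$families$MERVL$n_full)
})

test_that("a zero-element config yields genes only", {
  cfg <- fast_sim_config(5)
  for (f in names(cfg$families)) {
    cfg$families[[f]]$n_full <- 0L
    cfg$families[[f]]$n_solo <- 0L
  }
  cfg$genes$frac_near_mt2 <- 0
  cfg$chimeras <- list(n = 0L, support = integer(),
                       ltr_offset = c(1500L, 2500L))
  cfg$stages$n_2c_specific <- 2L
  g <- generate_toy_genome(cfg)
  expect_equal(nrow(g$repeats), 0L)
  expect_equal(nrow(g$gene_models$genes), cfg$genes$n)
  expect_equal(nrow(g$full_length), 0L)
})

test_that("RNA-seq pair counts are conserved and Poisson-calibrated", {
  cfg <- fast_sim_config(9)
  cfg$expression$noise <- "none"
  g <- generate_toy_genome(cfg)
  p <- simulate_rnaseq_pairs(g, "wt")
  planted <- attr(p, "planted_counts")
  expect_equal(nrow(p), sum(planted) + sum(g$truth$chimeras$support))

  # Poisson sampling: over replicate seeds the mean count of one element
  # matches its expectation within 3 standard errors
  cfg$expression$noise <- "poisson"
  cfg$expression$gene_base_pairs <- 0
  target <- g$full_length$element_id[1]
  expected <- cfg$expression$element_base_pairs
  n_rep <- 200L
  counts <- vapply(seq_len(n_rep), function(s) {
    c2 <- cfg; c2$seed <- 10000L + s
    attr(simulate_rnaseq_pairs(g, "wt", c2), "planted_counts")[[target]]
  }, 0L)
  se <- sqrt(expected / n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("planted chimeras appear as exactly the configured pairs", {
  cfg <- fast_sim_config(13)
  cfg$expression$noise <- "none"
  g <- generate_toy_genome(cfg)
  p <- simulate_rnaseq_pairs(g, "wt")
  fs <- estimate_fragment_stats(p)
  cand <- detect_chimeric_candidates(
    p, fs, g$repeats[g$repeats$part == "LTR", ], g$gene_models)
  truth <- g$truth$chimeras
  m <- merge(truth, cand, by = c("gene_id", "element_id"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$support.y, m$support.x)
})

test_that("simulated annotations parse through the package readers", {
  cfg <- fast_sim_config(31)
  g <- generate_toy_genome(cfg)
  bed <- withr::local_tempfile(fileext = ".bed")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_repeats_bed(g$repeats, bed)
  write_gene_models_gtf(g$gene_models, gtf)
  back <- read_repeat_annotation(bed, "bed6")
  expect_equal(back[c("family", "part", "chrom", "start", "end", "strand")],
               g$repeats[c("family", "part", "chrom", "start", "end",
                           "strand")],
               ignore_attr = TRUE)
  gm <- read_gene_models_gtf(gtf)
  expect_equal(gm$genes[order(gm$genes$gene_id),
                        c("gene_id", "chrom", "strand", "tss")],
               g$gene_models$genes[c("gene_id", "chrom", "strand", "tss")],
               ignore_attr = TRUE)

  sam <- withr::local_tempfile(fileext = ".sam")
  p <- simulate_rnaseq_pairs(g, "wt")
  write_sam_pairs(p, cfg$genome, sam)
  back_p <- read_sam_pairs(sam)
  expect_equal(nrow(back_p), nrow(p))
  expect_equal(sort(back_p$fragment), sort(p$fragment))
})

test_that("stage table plants 2C-specific genes recoverable at noise 0", {
  cfg <- fast_sim_config(19)
  cfg$stages$noise_sigma <- 0
  g <- generate_toy_genome(cfg)
  st <- simulate_stage_table(g)
  expect_equal(sort(classify_2c_specific(st)), g$truth$twoc_genes)

  # empty planted set -> classifier returns empty
  cfg2 <- cfg; cfg2$stages$n_2c_specific <- 0L
  g2 <- generate_toy_genome(cfg2)
  expect_equal(length(classify_2c_specific(simulate_stage_table(g2))), 0L)

  # deterministic bytes
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  utils::write.table(simulate_stage_table(g), f1)
  utils::write.table(simulate_stage_table(g), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the configured fraction of genes sits within 5 kb of an MT2", {
  cfg <- fast_sim_config(23)
  g <- generate_toy_genome(cfg)
  d <- nearest_ltr_distance(g$gene_models$genes, g$repeats)
  near <- names(d)[!is.na(d) & d <= 5000]
  expect_true(all(g$truth$near_mt2_genes %in% near))
})

test_that("zero reads requested yields empty ChIP output", {
  cfg <- fast_sim_config(3)
  cfg$chip$background_rate <- 0
  for (f in names(cfg$chip$profiles)) {
    cfg$chip$profiles[[f]]$enrichment <- 1
    cfg$chip$profiles[[f]]$half_length <- 0
  }
  g <- generate_toy_genome(cfg)
  expect_equal(nrow(simulate_chip_reads(g)), 0L)
})
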