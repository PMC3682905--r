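test_that("full-length assembly recognizes the canonical triplet", {
  fl <- assemble_full_length_elements(mervl_triplet())
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$superfamily, "MERVL")
  expect_equal(fl$start, 0L)
  expect_equal(fl$end, 6000L)
  expect_equal(fl$n_internal, 1L)
})

test_that("assembly rejects solo LTRs, mixed LTRs and bad spans", {
  solo <- mervl_triplet()[1, ]
  expect_equal(nrow(assemble_full_length_elements(solo)), 0L)

  mixed <- mervl_triplet()
  mixed$family[3] <- "RLTR10C"   # closing LTR of a different family
  mixed$part[3] <- "LTR"
  expect_equal(nrow(assemble_full_length_elements(mixed)), 0L)

  # span outside the MERVL 5-8 kb window is skipped and counted
  long <- mervl_triplet()
  long$end[2] <- 9000L; long$start[3] <- 9000L; long$end[3] <- 9500L
  res <- assemble_full_length_elements(long)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "skipped")[["MERVL"]], 1L)

  # gap above tolerance breaks the run
  gapped <- mervl_triplet()
  gapped$start[2] <- 700L   # 200 bp gap > 100 bp tolerance
  expect_equal(nrow(assemble_full_length_elements(gapped)), 0L)
})

test_that("assembled elements are non-overlapping and consume components", {
  reps <- rbind(mervl_triplet(0L), mervl_triplet(20000L),
                mervl_triplet(50000L, strand = "-"))
  fl <- assemble_full_length_elements(reps)
  expect_equal(nrow(fl), 3L)
  gr <- GenomicRanges::GRanges(fl$chrom,
                               IRanges::IRanges(fl$start + 1L, fl$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr)), 3L)
  # every element carries exactly two LTR components
  expect_true(all(fl$ltr5_id != fl$ltr3_id))
})

test_that("flank bin geometry matches the stated examples", {
  el <- data.frame(element_id = "x", chrom = "chr1", start = 10000L,
                   end = 16000L, strand = "+")
  b <- flank_bins(el)
  expect_equal(nrow(b), 240L)
  b5 <- b[b$side == "5prime" & b$bin_index == 0, ]
  b3 <- b[b$side == "3prime" & b$bin_index == 0, ]
  expect_equal(c(b5$start, b5$end), c(9950L, 10000L))
  expect_equal(c(b3$start, b3$end), c(16000L, 16050L))

  el$strand <- "-"
  bm <- flank_bins(el)
  b5m <- bm[bm$side == "5prime" & bm$bin_index == 0, ]
  expect_equal(c(b5m$start, b5m$end), c(16000L, 16050L))
  # strand mirror exactly reverses genomic order of a side
  expect_equal(bm$start[bm$side == "5prime"],
               b$start[b$side == "3prime"])

  # truncation at the chromosome edge
  el2 <- data.frame(element_id = "y", chrom = "chr1", start = 30L,
                    end = 6030L, strand = "+")
  bt <- flank_bins(el2)
  bt5 <- bt[bt$side == "5prime", ]
  expect_equal(sum(bt5$end - bt5$start), 30L)
  expect_true(any(bt5$truncated))

  expect_error(flank_bins(el, span = 0), "positive")
  expect_error(flank_bins(el, span = 6000, bin_width = 49), "divisible")
})

test_that("per-side bin widths sum to span minus truncation", {
  el <- data.frame(element_id = c("a", "b"), chrom = "chr1",
                   start = c(10000L, 7000L), end = c(16000L, 13000L),
                   strand = c("+", "-"))
  b <- flank_bins(el, chrom_lengths = c(chr1 = 20000L))
  agg <- tapply(b$end - b$start, paste(b$element_id, b$side), sum)
  expect_equal(agg[["a 5prime"]], 6000L)
  expect_equal(agg[["a 3prime"]], 4000L)  # clipped at the 20 kb chr end
  expect_equal(agg[["b 5prime"]], 6000L)
  expect_equal(agg[["b 3prime"]], 6000L)
})

test_that("nearest LTR distance: containment, gap, absence", {
  reps <- data.frame(element_id = "m1", family = "MT2_Mm",
                     erv_class = "III", part = "LTR", chrom = "chr1",
                     start = 1000L, end = 1500L, strand = "+",
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("inside", "far", "offchrom"),
                      chrom = c("chr1", "chr1", "chr2"),
                      tss = c(1200L, 10000L, 500L),
                      stringsAsFactors = FALSE)
  # spec geometry: nearest element ends at 5000, TSS at 10000 -> 5000
  reps2 <- rbind(reps, within(reps, {
    element_id <- "m2"; start <- 4500L; end <- 5000L
  }))
  d <- nearest_ltr_distance(genes, reps2)
  expect_equal(unname(d["inside"]), 0)
  expect_equal(unname(d["far"]), 5000)
  expect_true(is.na(d["offchrom"]))
})

test_that("nearest LTR distance is translation invariant", {
  set.seed(42)
  for (i in 1:5) {
    s <- sort(sample.int(50000L, 3))
    reps <- data.frame(element_id = paste0("m", 1:3), family = "MT2A",
                       erv_class = "III", part = "LTR", chrom = "chr1",
                       start = s, end = s + 400L, strand = "+",
                       stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = "g", chrom = "chr1",
                        tss = sample.int(60000L, 1))
    shift <- 12345L
    reps2 <- within(reps, {start <- start + shift; end <- end + shift})
    genes2 <- within(genes, tss <- tss + shift)
    expect_equal(nearest_ltr_distance(genes, reps),
                 nearest_ltr_distance(genes2, reps2))
  }
})
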