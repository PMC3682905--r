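chrlen <- c(chr1 = 50000L)

test_that("directional 300 bp extension from the 5' end", {
  # plus read 5' at 1000 -> [1000, 1300)
  tr <- build_coverage(make_reads("chr1", 1000L, 1036L, "+"), chrlen)
  cov <- as.integer(tr$cov$chr1)
  expect_equal(which(cov == 1L), 1001:1300)
  # minus read with rightmost base q = 2035 -> [1736, 2036)
  tr2 <- build_coverage(make_reads("chr1", 2000L, 2036L, "-"), chrlen)
  cov2 <- as.integer(tr2$cov$chr1)
  expect_equal(which(cov2 == 1L), 1737:2036)
  expect_error(build_coverage(make_reads("chr1", 1L, 37L), chrlen,
                              extension = 0), "positive")
})

test_that("duplicate collapsing is idempotent and strand-aware", {
  r <- make_reads("chr1", c(1000L, 1000L, 1000L), 1036L,
                  c("+", "+", "-"))
  tr <- build_coverage(r, chrlen)
  expect_equal(tr$library_total, 2L)  # one +, one - retained
  # injecting duplicates changes nothing
  tr2 <- build_coverage(rbind(r, r), chrlen)
  expect_identical(as.integer(tr$cov$chr1), as.integer(tr2$cov$chr1))
  # without dedup all three count
  tr3 <- build_coverage(r, chrlen, dedup = FALSE)
  expect_equal(tr3$library_total, 3L)
})

test_that("coverage mass equals retained reads x extension", {
  set.seed(11)
  r <- make_reads("chr1", sample(5000:40000, 50), 0L,
                  sample(c("+", "-"), 50, TRUE))
  r$end <- r$start + 36L
  r <- r[!duplicated(paste(r$start, r$strand)), ]
  tr <- build_coverage(r, chrlen)
  expect_equal(sum(as.numeric(tr$cov$chr1)), nrow(r) * 300)
})

test_that("threshold extracts maximal regions with inclusive cutoff", {
  reads <- make_reads("chr1", rep(1000L, 12), 1036L, "+")
  reads$qname <- sprintf("r%02d", 1:12)
  reads$start <- reads$start + rep(0:3, each = 3) # plateau of stacked reads
  tr <- build_coverage(reads, chrlen, dedup = FALSE)
  th <- threshold_coverage(tr, 10)
  expect_equal(nrow(th$regions), 1L)
  expect_equal(th$regions$max_height, 12)
  # thresholded track zeroes sub-threshold positions
  expect_true(all(as.integer(th$track$cov$chr1) %in% c(0L, 10:12)))

  none <- threshold_coverage(build_coverage(make_reads("chr1", 100L, 136L),
                                            chrlen), 10)
  expect_equal(nrow(none$regions), 0L)

  # exactly at the cutoff: single-base region retained
  stack <- make_reads("chr1", rep(500L, 10), 536L, "+")
  stack$qname <- sprintf("s%02d", 1:10)
  th2 <- threshold_coverage(build_coverage(stack, chrlen, dedup = FALSE), 10)
  expect_equal(nrow(th2$regions), 1L)
  expect_equal(th2$regions$max_height, 10)
})

test_that("WIG export round-trips through rtracklayer", {
  r <- make_reads("chr1", c(1000L, 5000L), 1036L, "+")
  tr <- build_coverage(r, chrlen)
  f <- withr::local_tempfile(fileext = ".wig")
  write_coverage_wig(tr, f)
  back <- rtracklayer::import(f)
  cov_back <- GenomicRanges::coverage(back, weight = "score")$chr1
  expect_equal(sum(as.numeric(cov_back)), sum(as.numeric(tr$cov$chr1)))
})

test_that("flank profile normalization matches the hand example", {
  el <- data.frame(element_id = "x", chrom = "chr1", start = 10000L,
                   end = 16000L, strand = "+", superfamily = "MERVL",
                   stringsAsFactors = FALSE)
  # + read 5' at 9700: extension [9700, 10000) fully covers 5' bin 0
  tr <- build_coverage(make_reads("chr1", 9700L, 9736L, "+"), chrlen)
  tr$library_total <- 1e6   # stated normalization example
  pr <- aggregate_flank_profile(tr, el)
  n <- length(pr$density) / 2
  expect_equal(pr$density[[n]], 1.0)       # 5' boundary bin
  expect_equal(sum(pr$density > 0), 6L)    # 300 bp = 6 bins
  expect_equal(pr$n_elements, 1L)

  empty <- build_coverage(make_reads(character(0), integer(0), integer(0)),
                          chrlen)
  empty$library_total <- 1e6
  expect_equal(sum(aggregate_flank_profile(empty, el)$density), 0)
  expect_error(aggregate_flank_profile(tr, el[0, ]), "n_elements")
})

test_that("strand mirror reverses the 240-bin vector", {
  set.seed(5)
  r <- make_reads("chr1", sample(4000:22000, 200), 0L,
                  sample(c("+", "-"), 200, TRUE))
  r$end <- r$start + 36L
  tr <- build_coverage(r, chrlen)
  el <- data.frame(element_id = "x", chrom = "chr1", start = 10000L,
                   end = 16000L, strand = "+", superfamily = "MERVL",
                   stringsAsFactors = FALSE)
  elm <- within(el, strand <- "-")
  expect_equal(aggregate_flank_profile(tr, elm)$density,
               rev(aggregate_flank_profile(tr, el)$density),
               ignore_attr = TRUE)
})

test_that("heatmap column means equal the aggregate profile exactly", {
  set.seed(6)
  r <- make_reads("chr1", sample(2000:46000, 400), 0L,
                  sample(c("+", "-"), 400, TRUE))
  r$end <- r$start + 36L
  tr <- build_coverage(r, chrlen)
  els <- data.frame(element_id = c("a", "b"), chrom = "chr1",
                    start = c(10000L, 30000L), end = c(16000L, 36000L),
                    strand = c("+", "-"), superfamily = "MERVL",
                    stringsAsFactors = FALSE)
  hm <- flank_heatmap(tr, els)
  pr <- aggregate_flank_profile(tr, els)
  expect_equal(unname(colMeans(hm$matrix)), unname(pr$density))
  # element order invariance of the aggregate
  pr2 <- aggregate_flank_profile(tr, els[2:1, ])
  expect_equal(pr$density, pr2$density)
  # split-and-average with element-count weights reproduces the aggregate
  pa <- aggregate_flank_profile(tr, els[1, , drop = FALSE])$density
  pb <- aggregate_flank_profile(tr, els[2, , drop = FALSE])$density
  expect_equal((pa + pb) / 2, pr$density)
})
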