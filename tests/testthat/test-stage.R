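test_that("RPM to RPKM conversion divides by length in kb", {
  expect_equal(rpm_to_rpkm(0, 2000), 0)
  expect_equal(rpm_to_rpkm(10, 2000), 5)
  expect_equal(rpm_to_rpkm(3, 1000), 3)
  expect_error(rpm_to_rpkm(1, 0), "> 0")
})

test_that("2C classification: inclusive 4-fold both ways plus floor", {
  tab <- data.frame(
    gene_id = c("in1", "edge", "out", "zero"),
    rpkm_oocyte = c(1, 1, 2, 0),
    rpkm_2c = c(5, 4, 7, 0.01),
    rpkm_8c = c(1, 1, 1, 0),
    stringsAsFactors = FALSE
  )
  got <- classify_2c_specific(tab)
  expect_true(all(c("in1", "edge") %in% got))   # "at least 4-fold" is >=
  expect_false("out" %in% got)                  # 7 < 4 x 2
  expect_false("zero" %in% got)                 # below the 0.5 floor

  # rpm input variant derives RPKM on the fly
  rpm_tab <- data.frame(gene_id = "g", rpm_oocyte = 1, rpm_2c = 8,
                        rpm_8c = 1, transcript_length = 1000)
  expect_equal(classify_2c_specific(rpm_tab), "g")
})

test_that("KO upregulation uses pseudocounted inclusive fold", {
  ko <- c(a = 4.1, b = 8, c = 0.2)
  wt <- c(a = 1.0, b = 1, c = 0.0)
  # a: (4.2/1.1) = 3.82 < 4 -> excluded by the pseudocount
  got <- upregulated_genes(ko, wt)
  expect_false("a" %in% got)
  expect_true("b" %in% got)
  # without pseudocount a crosses the line
  expect_true("a" %in% upregulated_genes(ko, wt, pseudocount = 1e-12))
  expect_equal(length(upregulated_genes(setNames(numeric(), character()),
                                        setNames(numeric(), character()))),
               0L)
  expect_error(upregulated_genes(ko, wt[1:2]), "universe")
})

test_that("overlap summary percentages and set algebra", {
  twoc <- sprintf("g%03d", 1:264)
  ups <- list(hp1a = sprintf("g%03d", 1:30),
              hp1b = sprintf("g%03d", 20:42))
  res <- overlap_summary(twoc, ups)
  expect_equal(res$union_overlap, 42L)
  expect_equal(res$union_percent, 16)
  expect_equal(res$per_set$overlap, c(30L, 23L))
  expect_equal(sort(res$all_lines_intersection), sprintf("g%03d", 20:30))

  expect_equal(overlap_summary(twoc, list(x = "zzz"))$union_percent, 0)
  expect_equal(overlap_summary(twoc, list(x = twoc))$union_percent, 100)

  # invariance under relabeling
  perm <- setNames(sprintf("h%03d", sample(300)), sprintf("g%03d", 1:300))
  res2 <- overlap_summary(unname(perm[twoc]),
                          lapply(ups, function(s) unname(perm[s])))
  expect_equal(res2$union_percent, res$union_percent)
  expect_equal(res2$per_set$overlap, res$per_set$overlap)
})

test_that("hypergeometric p-values match exhaustive enumeration", {
  # worked example: N=10, K=5, n=2, k=2 -> C(5,2)/C(10,2) = 10/45
  expect_equal(stats::phyper(1, 5, 5, 2, lower.tail = FALSE), 10 / 45)
  for (N in c(5L, 8L, 12L)) {
    for (K in c(0L, 2L, N %/% 2, N)) {
      for (n in c(1L, N %/% 3 + 1L, N)) {
        for (k in unique(c(0L, 1L, min(n, K)))) {
          expect_equal(
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
            hyper_upper_enum(k, K, N, n),
            tolerance = 1e-12,
            info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k)
          )
        }
      }
    }
  }
})

test_that("proximity enrichment counts, percentages and p-values", {
  reps <- data.frame(element_id = c("m1", "m2"), family = c("MT2_Mm", "MT2A"),
                     erv_class = "III", part = "LTR", chrom = "chr1",
                     start = c(1000L, 50000L), end = c(1500L, 50400L),
                     strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    chrom = "chr1",
    tss = c(1200L, 3000L, 6502L, 52000L, 100000L, 200000L),
    stringsAsFactors = FALSE
  )
  # proximal: g1 (inside), g2 (1500 bp), g4 (1600 bp); g3 is 5002 bp away
  res <- proximity_enrichment(c("g1", "g2", "g3"), genes, reps)
  expect_equal(res$background_count, 3L)
  expect_equal(res$overlap_count, 2L)
  expect_equal(res$percentage, 67)
  expect_equal(res$p_value,
               stats::phyper(1, 3, 3, 3, lower.tail = FALSE))

  none <- proximity_enrichment(character(), genes, reps)
  expect_equal(none$overlap_count, 0L)
  expect_equal(none$p_value, 1)

  # p decreases as a fully proximal set grows
  big_genes <- data.frame(gene_id = sprintf("G%02d", 1:40), chrom = "chr1",
                          tss = c(rep(1200L, 10), seq(80000, 370000,
                                                      by = 10000)),
                          stringsAsFactors = FALSE)
  ps <- vapply(c(2, 4, 8), function(n) {
    proximity_enrichment(sprintf("G%02d", 1:n), big_genes, reps)$p_value
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("inclusive 5 kb boundary for proximity", {
  reps <- data.frame(element_id = "m1", family = "MT2_Mm", erv_class = "III",
                     part = "LTR", chrom = "chr1", start = 0L, end = 500L,
                     strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("at", "past"), chrom = "chr1",
                      tss = c(5500L, 5501L), stringsAsFactors = FALSE)
  d <- nearest_ltr_distance(genes, reps)
  res_at <- proximity_enrichment("at", genes, reps)
  res_past <- proximity_enrichment("past", genes, reps)
  expect_equal(unname(d), c(5000, 5001))
  expect_equal(res_at$overlap_count, 1L)
  expect_equal(res_past$overlap_count, 0L)
})
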