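test_that("allelic-imbalance test reproduces the published worked examples", {
  ex <- worked_examples()
  p <- allelic_imbalance_test(ex$g_ref, ex$g_alt, ex$t_ref, ex$t_alt)
  expect_equal(signif(p, 3), signif(ex$p_printed, 3), tolerance = 1e-9)
  expect_equal(allelic_imbalance_test(50, 50, 50, 50), 1.0)
})

test_that("test is symmetric and p decreases with scaled evidence", {
  p1 <- allelic_imbalance_test(80, 64, 134, 177)
  expect_equal(allelic_imbalance_test(64, 80, 177, 134), p1)
  for (k in c(2, 3, 5)) {
    expect_lt(allelic_imbalance_test(80 * k, 64 * k, 134 * k, 177 * k), p1)
    p1 <- allelic_imbalance_test(80 * k, 64 * k, 134 * k, 177 * k)
  }
  expect_equal(allelic_imbalance_test(30, 30, 90, 90), 1.0)
  expect_warning(p0 <- allelic_imbalance_test(0, 0, 10, 20), "zero margin")
  expect_true(is.na(p0))
})

test_that("test agrees with stats::chisq.test on random tables", {
  set.seed(5)
  tabs <- matrix(sample(0:60, 4 * 400, replace = TRUE), ncol = 4)
  ok <- (tabs[, 1] + tabs[, 2]) > 0 & (tabs[, 3] + tabs[, 4]) > 0 &
    (tabs[, 1] + tabs[, 3]) > 0 & (tabs[, 2] + tabs[, 4]) > 0
  tabs <- tabs[ok, ]
  ours <- allelic_imbalance_test(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  ref <- apply(tabs, 1, function(x)
    suppressWarnings(stats::chisq.test(matrix(x, 2, byrow = TRUE),
                                       correct = FALSE)$p.value))
  expect_equal(ours, ref, tolerance = 1e-12)
  yates <- allelic_imbalance_test(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4],
                                  correct = TRUE)
  ref_y <- apply(tabs, 1, function(x)
    suppressWarnings(stats::chisq.test(matrix(x, 2, byrow = TRUE),
                                       correct = TRUE)$p.value))
  expect_equal(yates, ref_y, tolerance = 1e-12)
})

test_that("retention direction follows the tumor VAF shift", {
  expect_equal(retention_direction(80, 64, 134, 177), "variant-retained")
  expect_equal(retention_direction(64, 80, 177, 134), "wt-retained")
  expect_equal(retention_direction(50, 50, 30, 30), "balanced")
  expect_error(retention_direction(0, 0, 10, 10), "zero depth")
})

test_that("LOH typing requires significance, retention and minor 0", {
  expect_equal(classify_loh_type(0.001, "variant-retained", 2, 0), "CN-LOH")
  expect_equal(classify_loh_type(0.001, "variant-retained", 1, 0), "DEL-LOH")
  expect_equal(classify_loh_type(0.001, "variant-retained", 3, 0), "DUP-LOH")
  expect_equal(classify_loh_type(0.001, "variant-retained", 2, 1), "none")
  expect_equal(classify_loh_type(0.06, "variant-retained", 2, 0), "none")
  expect_equal(classify_loh_type(0.05, "variant-retained", 2, 0), "CN-LOH")
  expect_equal(classify_loh_type(0.001, "wt-retained", 1, 0), "none")
  expect_equal(classify_loh_type(NA, "variant-retained", 2, 0), "none")
})

test_that("segment lookup demands exactly one covering segment", {
  segs <- rbind(seg("chr1", 1, 100, 2, 1), seg("chr1", 101, 200, 1, 0))
  expect_equal(lookup_segment("chr1", 101, segs)$total_cn, 1)
  expect_equal(lookup_segment("chr1", 100, segs)$total_cn, 2)
  expect_error(lookup_segment("chr1", 500, segs), "uncovered")
  expect_error(lookup_segment("chr2", 50, segs), "uncovered")
  over <- rbind(seg("chr1", 1, 100, 2, 1), seg("chr1", 50, 200, 1, 0))
  expect_error(lookup_segment("chr1", 60, over), "overlapping")
})

test_that("somatic second point hits and biallelic scans follow consequence", {
  som <- rbind(
    make_somatic(gene = "GENEX", consequence = "nonsense", chrom = "chr1",
                 pos = 50L),
    make_somatic(gene = "GENEX", consequence = "synonymous", chrom = "chr1",
                 pos = 60L),
    make_somatic(gene = "GENEY", consequence = "splice", chrom = "chr1",
                 pos = 150L)
  )
  expect_match(detect_somatic_second_hit("GENEX", som), "chr1:50")
  expect_true(is.na(detect_somatic_second_hit("GENEZ", som)))
  gt <- data.frame(symbol = c("GENEX", "GENEY"), category = "C-HRG",
                   chrom = "chr1", pos = c(50L, 150L), start = c(1L, 101L),
                   end = c(100L, 200L), stringsAsFactors = FALSE)
  segs <- rbind(seg("chr1", 1, 100, 2, 1), seg("chr1", 101, 200, 3, 0))
  scan <- somatic_biallelic_scan(som, segs, gt)
  expect_equal(scan$gene, "GENEY")
  expect_equal(scan$retention, "DUP-LOH")
  expect_equal(nrow(somatic_biallelic_scan(som[0, ], segs, gt)), 0)
})

test_that("per-gene copy-number events follow the deletion/amplification rules", {
  gt <- data.frame(symbol = c("ERBB2", "PTEN", "GENEA", "GENEB"),
                   category = "other", chrom = "chr1",
                   pos = c(50L, 150L, 250L, 350L),
                   start = c(1L, 101L, 201L, 301L),
                   end = c(100L, 200L, 300L, 400L), stringsAsFactors = FALSE)
  segs <- rbind(seg("chr1", 1, 100, 7, 1), seg("chr1", 101, 200, 7, 1),
                seg("chr1", 201, 300, 1, 0), seg("chr1", 301, 400, 0, 0))
  ev <- call_cn_events(segs, gt)
  expect_equal(ev$event,
               c("amplification", "none", "hemizygous-deletion",
                 "homozygous-deletion"))
})

test_that("DEL-LOH loci are recovered from simulated counts", {
  set.seed(404)
  n <- 1000
  g <- simulate_read_counts(0.5, pmax(10, rpois(n, 141)))
  vaf <- expected_tumor_vaf(g$alt / (g$ref + g$alt), 0.6, 1, 1)
  t <- simulate_read_counts(vaf, pmax(10, rpois(n, 141)))
  p <- allelic_imbalance_test(g$ref, g$alt, t$ref, t$alt)
  dir_ <- retention_direction(g$ref, g$alt, t$ref, t$alt)
  type <- classify_loh_type(p, dir_, 1, 0)
  expect_gte(mean(type == "DEL-LOH"), 0.9)
})
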