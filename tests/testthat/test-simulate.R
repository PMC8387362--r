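test_that("read-count simulation has binomial and beta-binomial moments", {
  d <- simulate_read_counts(0.5, rep(200L, 10000), overdispersion = 0,
                            seed = 42)
  expect_true(all(d$ref + d$alt == 200))
  se <- sqrt(200 * 0.25 / 10000)
  expect_lt(abs(mean(d$alt) - 100), 3 * se)

  d0 <- simulate_read_counts(0, 50, seed = 1)
  expect_equal(c(d0$ref, d0$alt), c(50L, 0L))
  d1 <- simulate_read_counts(1, 50, overdispersion = 0.2, seed = 1)
  expect_equal(c(d1$ref, d1$alt), c(0L, 50L))

  db <- simulate_read_counts(0.5, rep(100L, 10000), overdispersion = 0.1,
                             seed = 7)
  target <- 100 * 0.25 * (1 + 99 * 0.1)
  expect_lt(abs(var(db$alt) - target) / target, 0.1)
})

test_that("read-count simulation rejects invalid parameters", {
  expect_error(simulate_read_counts(-0.1, 50), "allele_fraction")
  expect_error(simulate_read_counts(1.1, 50), "allele_fraction")
  expect_error(simulate_read_counts(0.5, -5), "depth")
  expect_error(simulate_read_counts(0.5, 50, overdispersion = 1), "overdispersion")
})

test_that("tumor VAF follows the purity and copy-number mixture", {
  expect_equal(expected_tumor_vaf(0.5, 1, 2, 2), 1)
  expect_equal(expected_tumor_vaf(0.5, 0.5, 1, 1), 2 / 3)
  expect_equal(expected_tumor_vaf(0.5, 0, 3, 0), 0.5)
  expect_error(expected_tumor_vaf(0.5, 0.5, 2, 3), "variant_cn")
  d <- simulate_tumor_counts_at_locus(0.5, 1, 2, 2, depth = 80, seed = 3)
  expect_equal(d$alt, 80L)
  expect_error(simulate_tumor_counts_at_locus(0.5, 1.2, 2, 1, 50), "purity")
})

test_that("catalog simulation is multinomial and conserves counts", {
  M <- synthetic_signatures()
  e <- setNames(numeric(6), colnames(M)); e["Signature 1"] <- 1
  cat_ <- simulate_catalog(e, 10000, M, seed = 11)
  expect_equal(sum(cat_), 10000)
  expect_lt(max(abs(cat_ / 10000 - M[, "Signature 1"])), 0.01)
  expect_equal(sum(simulate_catalog(e, 0, M)), 0)
  e2 <- e; e2["Signature 1"] <- 0.9
  expect_error(simulate_catalog(e2, 100, M), "sum to 1")
})

test_that("segment simulation hits scar targets exactly and errors when infeasible", {
  lay <- default_genome_layout()
  for (tg in list(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(0, 0, 3),
                  c(20, 15, 8), c(5, 5, 5))) {
    s <- simulate_segments(tg, lay)
    expect_identical(
      c(score_hrd_loh(s, lay), score_lst(s, lay), score_tai(s, lay)),
      as.integer(tg))
  }
  expect_error(simulate_segments(c(0, 0, 100), lay), "not achievable")
})

test_that("FFPE artifact injection is strand-skewed C>T and rate-0 is identity", {
  som <- make_somatic()
  out0 <- inject_ffpe_artifacts(som, rate = 0, seed = 1)
  expect_identical(out0$variants, som)
  expect_equal(nrow(out0$artifacts), 0)
  out <- inject_ffpe_artifacts(som, rate = 3, seed = 5, patient_id = "P001")
  art <- out$variants[-1, ]
  expect_gt(nrow(art), 0)
  expect_true(all(paste0(art$ref, ">", art$alt) %in% c("C>T", "G>A")))
  skew <- pmax(art$alt_fwd, art$alt_rev) / (art$alt_fwd + art$alt_rev)
  expect_true(all(skew >= 0.9))
})

test_that("spiked scenario carries the full causal construct", {
  sp <- spike_causal_scenario(list(patient_id = "P9"), "RAD51D", seed = 21)
  p <- sp$patient
  v <- p$germline[p$germline$gene == "RAD51D", ]
  expect_equal(nrow(v), 1)
  af <- v$g_alt / (v$g_ref + v$g_alt)
  expect_true(af >= 0.35 && af <= 0.5)
  seg <- lookup_segment(v$chrom, v$pos, p$segments)
  expect_equal(c(seg$total_cn, seg$minor_cn), c(2, 0))
  lay <- default_genome_layout()
  expect_gte(score_hrd_loh(p$segments, lay) + score_lst(p$segments, lay) +
               score_tai(p$segments, lay), 42)
  expect_error(spike_causal_scenario(list(patient_id = "P9"), "NOSUCH"),
               "not present")
})

test_that("spiked loci show allelic imbalance in nearly all replicates", {
  cfg <- simulation_config()
  hits <- vapply(1:100, function(i) {
    sp <- spike_causal_scenario(list(patient_id = "X"), "RAD51D",
                                config = cfg, seed = i)
    v <- sp$patient$germline[1, ]
    p <- allelic_imbalance_test(v$g_ref, v$g_alt, v$t_ref, v$t_alt)
    p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohorts are deterministic in the seed and record every spike", {
  cfg <- simulation_config(n_patients = 6, seed = 123, causal_fraction = 0.5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$germline, c2$germline)
  expect_identical(c1$somatic, c2$somatic)
  expect_identical(c1$segments, c2$segments)
  expect_equal(sum(c1$truth$patients$spiked), round(0.5 * 6))
  c3 <- simulate_cohort(simulation_config(n_patients = 6, seed = 124,
                                          causal_fraction = 0.5))
  expect_false(identical(c1$somatic, c3$somatic))
  # read pairs conserve depth; no ground-truth column leaks into the tables
  expect_true(all(c1$somatic$t_ref + c1$somatic$t_alt > 0))
  expect_false(any(grepl("artifact|spike|truth", names(c1$somatic))))
})
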