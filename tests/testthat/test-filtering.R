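test_that("germline quality rules fire in order with documented boundaries", {
  cases <- rbind(
    make_variant(g_ref = 2L, g_alt = 2L),                      # depth 4
    make_variant(g_ref = 3L, g_alt = 2L),                      # depth 5, AF .4
    make_variant(g_ref = 8L, g_alt = 1L),                      # alt 1
    make_variant(g_ref = 80L, g_alt = 20L),                    # AF 0.2
    make_variant(g_ref = 60L, g_alt = 50L),                    # AF .455 kept
    make_variant(g_ref = 50L, g_alt = 50L),                    # AF .5 kept
    make_variant(g_ref = 65L, g_alt = 35L),                    # AF .35 kept
    make_variant(g_ref = 40L, g_alt = 60L),                    # AF .6
    make_variant(g_ref = 60L, g_alt = 50L, mq = 29),           # MQ
    make_variant(g_ref = NA_integer_, g_alt = NA_integer_)     # unscorable
  )
  out <- filter_germline_quality(cases)
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(cases))
  expect_equal(out$removed$reason,
               c("i", "ii", "iii", "iii", "iv", "unscorable"))
  expect_equal(out$kept$g_alt, c(2L, 50L, 50L, 35L))
})

test_that("population frequency cutoff is strict and missing means rare", {
  v <- rbind(make_variant(pop_af = 0.009), make_variant(pop_af = 0.01),
             make_variant(pop_af = NA_real_), make_variant(pop_af = 0.5))
  kept <- filter_population_frequency(v)
  expect_equal(kept$pop_af, c(0.009, NA))
  # monotonicity: a larger threshold never removes a previously kept variant
  kept2 <- filter_population_frequency(v, threshold = 0.05)
  expect_true(all(paste(kept$pos, kept$pop_af) %in%
                    paste(kept2$pos, kept2$pop_af)))
})

test_that("predictor consensus needs 4 of 8, absent counting against", {
  expect_true(predictor_consensus(c(rep(TRUE, 4), rep(FALSE, 4))))
  expect_false(predictor_consensus(c(rep(TRUE, 3), rep(FALSE, 5))))
  expect_true(predictor_consensus(rep(TRUE, 8)))
  expect_false(predictor_consensus(c(rep(TRUE, 3), rep(NA, 5))))
  expect_error(predictor_consensus(rep(TRUE, 9)), "more than 8")
})

test_that("candidate routing follows the ClinVar/ACMG and category rules", {
  five_of8 <- function(v) {
    for (p in hrdtwohit:::predictor_columns) v[[p]] <- FALSE
    v$sift <- v$polyphen2 <- v$mutationtaster <- v$fathmm <- v$provean <- TRUE
    v
  }
  v1 <- five_of8(make_variant(clinvar = "Unknown", acmg = "VUS"))
  expect_equal(route_candidate(v1, "C-HRG"), "master-list")
  v2 <- make_variant(clinvar = "VUS")
  for (p in hrdtwohit:::predictor_columns) v2[[p]] <- FALSE
  expect_equal(route_candidate(v2, "BCSG"), "master-list")
  v3 <- make_variant(clinvar = "Likely benign")
  expect_equal(route_candidate(v3, "C-HRG"), "dropped-benign")
  # ACMG screens when ClinVar is absent
  v4 <- make_variant(clinvar = "Unknown", acmg = "Likely benign")
  expect_equal(route_candidate(v4, "C-HRG"), "dropped-benign")
  v5 <- make_variant(consequence = "nonsense", clinvar = "Unknown")
  for (p in hrdtwohit:::predictor_columns) v5[[p]] <- FALSE
  expect_equal(route_candidate(v5, "C-HRG"), "master-list")
  v6 <- make_variant(consequence = "synonymous")
  expect_equal(route_candidate(v6, "C-HRG"), "dropped-consequence")
  v7 <- five_of8(make_variant(clinvar = "Unknown", acmg = "VUS"))
  v7$sift <- FALSE # 4 of 8
  expect_equal(route_candidate(v7, "DNA-repair"), "master-list")
  v7$polyphen2 <- FALSE # 3 of 8
  expect_equal(route_candidate(v7, "DNA-repair"), "dropped-prediction")
})

test_that("gene categories resolve by precedence with unknowns as other", {
  gt <- default_gene_table()
  expect_equal(assign_gene_category("CHEK2", gt), "BCSG")
  expect_equal(assign_gene_category("REV1", gt), "DNA-repair")
  expect_equal(assign_gene_category("TOTALLYNOVEL", gt), "other")
  dup <- rbind(gt, data.frame(symbol = "CHEK2", category = "C-HRG",
                              chrom = "chr22", pos = 1e6, start = 1,
                              end = 2e6))
  expect_equal(assign_gene_category("CHEK2", dup), "BCSG")
})

test_that("somatic filter enforces the four contracts in order", {
  pon <- data.frame(chrom = "chr9", pos = 500L, ref = "C", alt = "T",
                    stringsAsFactors = FALSE)
  germ <- make_variant(chrom = "chr5", pos = 100L)
  cases <- rbind(
    make_somatic(t_ref = 5L, t_alt = 4L),                      # depth 9
    make_somatic(alt_fwd = 12L, alt_rev = 0L, t_alt = 12L, t_ref = 100L),
    make_somatic(chrom = "chr9", pos = 500L),                  # PoN
    make_somatic(chrom = "chr5", pos = 100L),                  # germline
    make_somatic(t_ref = 50L, t_alt = 30L)                     # kept
  )
  out <- filter_somatic(cases, pon = pon, matched_germline = germ)
  expect_equal(nrow(out$kept), 1)
  expect_setequal(out$removed$reason, c("iv", "i", "iii", "ii"))
  expect_equal(out$removed$reason[out$removed$pos == 500], "iii")
  # partition and order-independence
  sh <- c(3, 5, 1, 4, 2)
  out2 <- filter_somatic(cases[sh, ], pon = pon, matched_germline = germ)
  expect_equal(sort(out2$removed$reason), sort(out$removed$reason))
  expect_equal(nrow(out2$kept) + nrow(out2$removed), nrow(cases))
})

test_that("simulated artifacts are removed and true somatic SNVs survive", {
  cfg <- simulation_config(n_patients = 10, seed = 31)
  coh <- simulate_cohort(cfg)
  out <- filter_somatic(coh$somatic, pon = coh$pon,
                        matched_germline = coh$germline)
  akey <- paste(coh$truth$artifacts$patient_id, coh$truth$artifacts$chrom,
                coh$truth$artifacts$pos)
  rkey <- paste(out$removed$patient_id, out$removed$chrom, out$removed$pos)
  expect_gte(mean(akey %in% rkey), 0.95)
  skey <- paste(coh$somatic$patient_id, coh$somatic$chrom, coh$somatic$pos)
  true_key <- setdiff(skey, akey)
  vaf <- coh$somatic$t_alt / (coh$somatic$t_ref + coh$somatic$t_alt)
  good <- skey %in% true_key & vaf >= 0.2 &
    (coh$somatic$t_ref + coh$somatic$t_alt) >= 30
  expect_gte(mean(skey[good] %in%
                    paste(out$kept$patient_id, out$kept$chrom,
                          out$kept$pos)), 0.95)
})
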