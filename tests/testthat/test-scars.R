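# hand-enumerable segment fixtures on the two-chromosome tiny layout

test_that("HRD-LOH counts long sub-chromosomal LOH regions only", {
  lay <- tiny_layout()
  segs <- rbind(
    seg("chrA", 1, 30e6, 2, 1),
    seg("chrA", 30e6 + 1, 50e6, 2, 0),   # 20 Mb LOH -> counts
    seg("chrA", 50e6 + 1, 140e6, 2, 1),
    seg("chrA", 140e6 + 1, 150e6, 1, 0), # 10 Mb LOH -> below cutoff
    seg("chrB", 1, 100e6, 3, 0)          # whole-chromosome LOH -> excluded
  )
  expect_equal(score_hrd_loh(segs, lay), 1)
  three <- rbind(
    seg("chrA", 1, 5e6, 2, 1), seg("chrA", 5e6 + 1, 25e6, 2, 0),
    seg("chrA", 25e6 + 1, 30e6, 2, 1), seg("chrA", 30e6 + 1, 50e6, 1, 0),
    seg("chrA", 50e6 + 1, 150e6, 2, 1),
    seg("chrB", 1, 10e6, 2, 1), seg("chrB", 10e6 + 1, 30e6, 2, 0),
    seg("chrB", 30e6 + 1, 100e6, 2, 1)
  )
  expect_equal(score_hrd_loh(three, lay), 3)
  # adjacent LOH segments with different totals merge into one region
  merged <- rbind(seg("chrA", 1, 20e6, 2, 1),
                  seg("chrA", 20e6 + 1, 30e6, 2, 0),
                  seg("chrA", 30e6 + 1, 40e6, 1, 0),
                  seg("chrA", 40e6 + 1, 150e6, 2, 1))
  expect_equal(score_hrd_loh(merged, lay), 1)
})

test_that("LST counts breakpoints between long segments after 3 Mb smoothing", {
  lay <- tiny_layout()
  two <- rbind(seg("chrA", 1, 12e6, 2, 1),
               seg("chrA", 12e6 + 1, 24e6, 4, 2),
               seg("chrA", 24e6 + 1, 150e6, 4, 2))
  expect_equal(score_lst(two, lay), 1)
  expect_equal(score_lst(seg("chrA", 1, 150e6, 2, 1), lay), 0)
  # a 2 Mb interruption between same-state flanks is smoothed away
  interrupted <- rbind(seg("chrA", 1, 12e6, 2, 1),
                       seg("chrA", 12e6 + 1, 14e6, 3, 1),
                       seg("chrA", 14e6 + 1, 26e6, 2, 1),
                       seg("chrA", 26e6 + 1, 150e6, 2, 1))
  expect_equal(score_lst(interrupted, lay), 0)
  # but with differing flanks the breakpoint survives smoothing
  diff_flanks <- rbind(seg("chrA", 1, 12e6, 2, 1),
                       seg("chrA", 12e6 + 1, 14e6, 3, 1),
                       seg("chrA", 14e6 + 1, 26e6, 4, 2),
                       seg("chrA", 26e6 + 1, 150e6, 4, 2))
  expect_equal(score_lst(diff_flanks, lay), 1)
  # short flank (< 10 Mb) disqualifies the breakpoint
  short <- rbind(seg("chrA", 1, 8e6, 4, 2),
                 seg("chrA", 8e6 + 1, 150e6, 2, 1))
  expect_equal(score_lst(short, lay), 0)
})

test_that("TAI counts telomeric imbalance not crossing the centromere", {
  lay <- tiny_layout() # chrA centromere at 60 Mb
  one <- rbind(seg("chrA", 1, 30e6, 3, 1),
               seg("chrA", 30e6 + 1, 150e6, 2, 1))
  expect_equal(score_tai(one, lay), 1)
  crossing <- rbind(seg("chrA", 1, 70e6, 3, 1),
                    seg("chrA", 70e6 + 1, 150e6, 2, 1))
  expect_equal(score_tai(crossing, lay), 0)
  balanced <- seg("chrA", 1, 150e6, 2, 1)
  expect_equal(score_tai(balanced, lay), 0)
  # interior AI is not telomeric
  interior <- rbind(seg("chrA", 1, 30e6, 2, 1),
                    seg("chrA", 30e6 + 1, 50e6, 3, 1),
                    seg("chrA", 50e6 + 1, 150e6, 2, 1))
  expect_equal(score_tai(interior, lay), 0)
  # both telomeres can contribute
  both <- rbind(seg("chrA", 1, 20e6, 3, 1),
                seg("chrA", 20e6 + 1, 130e6, 2, 1),
                seg("chrA", 130e6 + 1, 150e6, 3, 1))
  expect_equal(score_tai(both, lay), 2)
})

test_that("scar scores are invariant under state-preserving segment splits", {
  lay <- default_genome_layout()
  segs <- simulate_segments(c(4, 3, 2), lay)
  split_segs <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    if (s$end - s$start > 2) {
      mid <- floor((s$start + s$end) / 2)
      rbind(seg(s$chrom, s$start, mid, s$total_cn, s$minor_cn),
            seg(s$chrom, mid + 1, s$end, s$total_cn, s$minor_cn))
    } else s[, c("chrom", "start", "end", "total_cn", "minor_cn")]
  }))
  expect_equal(score_hrd_loh(split_segs, lay), score_hrd_loh(segs, lay))
  expect_equal(score_lst(split_segs, lay), score_lst(segs, lay))
  expect_equal(score_tai(split_segs, lay), score_tai(segs, lay))
})

test_that("scar call threshold is inclusive at 42", {
  expect_true(call_scar_hrd(20, 15, 8))   # 43
  expect_false(call_scar_hrd(14, 14, 13)) # 41
  expect_true(call_scar_hrd(42, 0, 0))    # 42
  expect_false(call_scar_hrd(14, 14, 13, threshold = 42))
  expect_true(call_scar_hrd(0, 0, 0, threshold = 0))
  expect_error(call_scar_hrd(-1, 0, 0))
})

test_that("consensus is a logical AND with no-call propagation", {
  expect_true(consensus_hrd(TRUE, TRUE))
  expect_false(consensus_hrd(FALSE, TRUE))
  expect_false(consensus_hrd(TRUE, FALSE))
  expect_false(consensus_hrd(FALSE, FALSE))
  expect_true(is.na(consensus_hrd(NA, TRUE)))
  expect_true(is.na(consensus_hrd(NA, FALSE))) # no-call, never negative
  expect_true(is.na(consensus_hrd(TRUE, NA)))
})
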