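ann100 <- toy_genome()  # chr1: 100 Mb, centromere 45-50 Mb

test_that("HRD-LOH counts long sub-chromosomal LOH segments", {
  # 20 Mb LOH segment on a 100 Mb chromosome
  expect_equal(compute_hrd_loh(mk_profile(list("chr1", 50.1e6, 70.1e6 - 1, 2, 2, 0)),
                               ann100), 1)
  # whole-chromosome LOH excluded
  expect_equal(compute_hrd_loh(mk_profile(list("chr1", 1, 100e6, 1, 1, 0)),
                               ann100), 0)
  # below the 15 Mb threshold
  expect_equal(compute_hrd_loh(mk_profile(list("chr1", 50e6, 60e6 - 1, 2, 2, 0)),
                               ann100), 0)
  # heterozygous segments never count
  expect_equal(compute_hrd_loh(mk_profile(list("chr1", 50e6, 90e6, 2, 1, 1)),
                               ann100), 0)
})

test_that("NtAI requires telomeric, centromere-confined allelic imbalance", {
  # 30 Mb AI segment abutting the q terminus
  expect_equal(compute_ntai(mk_profile(list("chr1", 70e6 + 1, 100e6, 3, 2, 1)),
                            ann100), 1)
  # p-terminal AI also counts
  expect_equal(compute_ntai(mk_profile(list("chr1", 1, 6e6, 3, 2, 1)),
                            ann100), 1)
  # spanning the centromere to the telomere is excluded
  expect_equal(compute_ntai(mk_profile(list("chr1", 40e6, 100e6, 3, 2, 1)),
                            ann100), 0)
  # interstitial AI is excluded
  expect_equal(compute_ntai(mk_profile(list("chr1", 60e6, 80e6, 2, 2, 0)),
                            ann100), 0)
  # balanced telomeric segments are excluded
  expect_equal(compute_ntai(mk_profile(list("chr1", 80e6, 100e6, 4, 2, 2)),
                            ann100), 0)
  # below minimum length
  expect_equal(compute_ntai(mk_profile(list("chr1", 99.5e6, 100e6, 3, 2, 1)),
                            ann100), 0)
})

test_that("LST counts breakpoints between large segments after smoothing", {
  # two adjacent 15 Mb segments with a state change
  expect_equal(compute_lst(mk_profile(list("chr1", 1, 15e6, 2, 1, 1),
                                      list("chr1", 15e6 + 1, 30e6, 3, 2, 1))), 1)
  # a 2 Mb interloper is smoothed away and the flanks merge into one state
  expect_equal(compute_lst(mk_profile(list("chr1", 1, 15e6, 2, 1, 1),
                                      list("chr1", 15e6 + 1, 17e6, 3, 3, 0),
                                      list("chr1", 17e6 + 1, 32e6, 2, 1, 1))), 0)
  # uniform diploid chromosome
  expect_equal(compute_lst(diploid_profile(ann100)), 0)
  # a gap of >= 3 Mb between the large segments suppresses the breakpoint
  expect_equal(compute_lst(mk_profile(list("chr1", 1, 15e6, 2, 1, 1),
                                      list("chr1", 19e6, 34e6, 3, 2, 1))), 0)
  # flank below 10 Mb does not qualify
  expect_equal(compute_lst(mk_profile(list("chr1", 1, 8e6, 2, 1, 1),
                                      list("chr1", 8e6 + 1, 30e6, 3, 2, 1))), 0)
})

test_that("LST is invariant under splitting a segment into same-state pieces", {
  set.seed(3)
  for (rep in 1:25) {
    p <- random_profile()
    base <- compute_lst(p)
    seg <- p$segments
    i <- sample.int(nrow(seg), 1)
    if (seg$end[i] - seg$start[i] < 2) next
    cut <- seg$start[i] + sample.int(seg$end[i] - seg$start[i] - 1, 1)
    split_seg <- rbind(
      seg[seq_len(i - 1), , drop = FALSE],
      transform(seg[i, ], end = cut),
      transform(seg[i, ], start = cut + 1),
      seg[setdiff(seq_len(nrow(seg)), seq_len(i)), , drop = FALSE])
    p2 <- segment_profile(split_seg, p$sample_id, p$purity, p$ploidy)
    expect_equal(compute_lst(p2), base)
  }
})

test_that("aneuploidy counts arms mostly shifted away from sample ploidy", {
  expect_equal(compute_aneuploidy(diploid_profile(ann100), ann100), 0)
  # whole p arm at total CN 3 in a ploidy-2 sample
  p_arm <- mk_profile(list("chr1", 1, 45e6, 3, 2, 1))
  expect_equal(compute_aneuploidy(p_arm, ann100), 1)
  # 50% of the arm altered is below the 80% coverage rule
  half <- mk_profile(list("chr1", 1, 22.5e6, 3, 2, 1))
  expect_equal(compute_aneuploidy(half, ann100), 0)
  # both arms altered -> 2
  both <- mk_profile(list("chr1", 1, 45e6, 3, 2, 1),
                     list("chr1", 50e6 + 1, 100e6, 4, 2, 2))
  expect_equal(compute_aneuploidy(both, ann100), 2)
  # ploidy is rounded before comparison: near-triploid sample, CN 3 is base
  tri <- segment_profile(mk_segments(list("chr1", 1, 45e6, 3, 2, 1)),
                         "S1", 1, 2.8)
  expect_equal(compute_aneuploidy(tri, ann100), 0)
})

test_that("TMB is the exact quotient of counts over capture size", {
  expect_equal(compute_tmb(0, 50), 0)
  expect_equal(compute_tmb(64, 50), 1.28)
  expect_equal(compute_tmb(640, 50), 12.8)
  expect_error(compute_tmb(10, 0), "capture size")
  expect_error(compute_tmb(-1, 50), ">= 0")
})

test_that("hrd_sum is conserved and appending a qualifying LOH segment adds one", {
  set.seed(11)
  for (rep in 1:20) {
    p <- random_profile()
    sc <- compute_scar_scores(p, random_profile_genome())
    expect_equal(sc$hrd_sum, sc$ntai + sc$lst + sc$hrd_loh)
  }
  # monotonicity: a new isolated 20 Mb interstitial LOH island on a fresh
  # chromosome adds exactly 1 to hrd_loh and never decreases ntai/lst
  ann <- random_profile_genome()
  set.seed(12)
  for (rep in 1:10) {
    p <- random_profile(genome_annotation("chr1", 120e6, 50e6, 56e6 + 1))
    ann1 <- genome_annotation(c("chr1", "chr2"), c(120e6, 80e6),
                              c(50e6, 30e6), c(56e6 + 1, 35e6 + 1))
    before <- compute_scar_scores(p, ann1)
    seg2 <- rbind(p$segments,
                  data.frame(chrom = "chr2", start = 40e6, end = 60e6 - 1,
                             cn_total = 2, cn_major = 2, cn_minor = 0))
    p2 <- segment_profile(seg2, p$sample_id, p$purity, p$ploidy)
    after <- compute_scar_scores(p2, ann1)
    expect_equal(after$hrd_loh, before$hrd_loh + 1)
    expect_gte(after$ntai, before$ntai)
    expect_gte(after$lst, before$lst)
  }
})

test_that("signed-rank test handles zeros, shifts and the single pair", {
  # identical scores -> all zero differences -> p = 1
  w <- wilcoxon_signed_rank(rep(3, 10), rep(3, 10))
  expect_equal(w$p_value, 1)
  # constant +5 recurrence shift at n = 20 is clearly significant
  x <- 1:20
  w <- wilcoxon_signed_rank(x, x + 5)
  expect_lt(w$p_value, 0.01)
  # n = 1 nonzero pair: trivial two-sided exact p of 1
  expect_equal(wilcoxon_signed_rank(0, 5)$p_value, 1)
  # agrees with stats::wilcox.test on zero-free untied data
  set.seed(5)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  # large-sample branch tracks the wilcox.test normal approximation
  x <- rnorm(50); y <- x + rnorm(50, 0.3)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("paired comparison picks one seeded recurrence per patient", {
  meta <- mk_metadata(n_pat = 6, recs = 3)
  scores <- data.frame(sample_id = meta$sample_id,
                       ntai = seq_len(nrow(meta)),
                       lst = 1, hrd_loh = 0, hrd_sum = seq_len(nrow(meta)) + 1,
                       aneuploidy = 0, tmb = 1.5)
  r1 <- compare_paired_scores(scores, meta, seed = 9)
  r2 <- compare_paired_scores(scores, meta, seed = 9)
  expect_identical(r1$pairs, r2$pairs)  # seeded choice is reproducible
  expect_equal(nrow(r1$pairs), 6)
  expect_true(all(r1$pairs$recurrent_sample %in%
                    meta$sample_id[meta$group == "recurrent"]))
  # constant metric -> all-zero differences -> p = 1
  expect_equal(r1$tests$p_value[r1$tests$metric == "lst"], 1)
  expect_error(compare_paired_scores(scores[0, ], meta[0, ]),
               "missing column|no patient")
})
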