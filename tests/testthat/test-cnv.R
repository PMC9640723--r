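test_that("copy-number binning is total and surjective over 0..6", {
  expect_equal(bin_copy_number(0), "Deletion")
  expect_equal(bin_copy_number(1), "Loss")
  expect_equal(bin_copy_number(2), "Neutral")
  expect_equal(bin_copy_number(3), "Neutral")
  expect_equal(bin_copy_number(4), "Gain")
  expect_equal(bin_copy_number(5), "Gain")
  expect_equal(bin_copy_number(6), "Amplification")
  expect_equal(bin_copy_number(7), "Amplification")
  expect_setequal(bin_copy_number(0:6),
                  c("Deletion", "Loss", "Neutral", "Gain", "Amplification"))
  expect_error(bin_copy_number(-1), ">= 0")
})

test_that("gene-level CN uses minimal copy number and strict coverage rules", {
  gene <- data.frame(gene = "G1", chrom = "chr1", start = 1000, end = 2000)

  # fully inside one CN=4 segment
  call <- annotate_gene_cn(gene, mk_profile(list("chr1", 1, 10000, 4, 2, 2)))
  expect_equal(call$min_cn, 4)
  expect_equal(call$category, "Gain")
  expect_false(call$qualifies_amplified)

  # 60% CN=6 + 40% CN=2: min rule gives 2, amplification needs 100%
  p <- mk_profile(list("chr1", 1, 1600, 6, 3, 3),
                  list("chr1", 1601, 3000, 2, 1, 1))
  call <- annotate_gene_cn(gene, p)
  expect_equal(call$min_cn, 2)
  expect_false(call$qualifies_amplified)
  expect_equal(call$amplification_fraction, 0.6, tolerance = 1e-3)

  # 70% covered by a deletion -> qualifies_deleted
  p <- mk_profile(list("chr1", 1, 1700, 0, 0, 0))
  call <- annotate_gene_cn(gene, p)
  expect_true(call$qualifies_deleted)
  expect_equal(call$covered_fraction, 0.7, tolerance = 1e-3)

  # 100% amplification coverage -> qualifies_amplified
  call <- annotate_gene_cn(gene, mk_profile(list("chr1", 1, 5000, 6, 3, 3)))
  expect_true(call$qualifies_amplified)

  # no covering segment -> no-call with warning
  expect_warning(
    call <- annotate_gene_cn(gene, mk_profile(list("chr2", 1, 5000, 2, 1, 1))),
    "no-call")
  expect_true(is.na(call$min_cn))

  # invariant to splitting a covering segment into same-CN pieces
  whole <- annotate_gene_cn(gene, mk_profile(list("chr1", 1, 5000, 4, 2, 2)))
  split <- annotate_gene_cn(gene, mk_profile(list("chr1", 1, 1500, 4, 2, 2),
                                             list("chr1", 1501, 5000, 4, 2, 2)))
  expect_equal(split[, -1], whole[, -1])
})

test_that("reciprocal overlap and segment-set comparison follow BEDtools semantics", {
  a <- list(chrom = "chr1", start = 1, end = 100)
  b <- list(chrom = "chr1", start = 41, end = 140)
  # 60 bp intersection is 60% of each 100 bp interval
  expect_true(reciprocal_overlap(a, b, f = 0.5))
  expect_false(reciprocal_overlap(a, b, f = 0.7))
  expect_false(reciprocal_overlap(a, list(chrom = "chr2", start = 1, end = 100)))

  set <- data.frame(chrom = "chr1", start = c(1, 500), end = c(100, 900))
  # identical sets: everything shared, Jaccard 1
  cmp <- compare_segment_sets(set, set)
  expect_equal(nrow(cmp$shared), 2)
  expect_equal(nrow(cmp$private_a), 0)
  expect_equal(cmp$jaccard, 1)

  # disjoint sets: everything private, Jaccard 0
  other <- data.frame(chrom = "chr1", start = c(2000, 3000), end = c(2100, 3100))
  cmp <- compare_segment_sets(set, other)
  expect_equal(nrow(cmp$shared), 0)
  expect_equal(nrow(cmp$private_a), 2)
  expect_equal(nrow(cmp$private_b), 2)
  expect_equal(cmp$jaccard, 0)

  # partition invariant + symmetry
  set.seed(21)
  for (rep in 1:20) {
    mk_set <- function(n) {
      s <- sort(sample.int(5000, 2 * n))
      data.frame(chrom = "chr1", start = s[seq(1, 2 * n, 2)],
                 end = s[seq(2, 2 * n, 2)])
    }
    A <- mk_set(sample.int(6, 1)); B <- mk_set(sample.int(6, 1))
    ab <- compare_segment_sets(A, B)
    ba <- compare_segment_sets(B, A)
    expect_equal(nrow(ab$shared) + nrow(ab$private_a), nrow(A))
    expect_equal(nrow(ab$shared) + nrow(ab$private_b), nrow(B))
    expect_equal(ab$jaccard, ba$jaccard)
  }
})

test_that("minimal common region matches the spec examples and the per-bp oracle", {
  ivs <- function(...) lapply(list(...), function(m) {
    data.frame(chrom = "chr1", start = m[c(TRUE, FALSE)], end = m[c(FALSE, TRUE)])
  })
  # three identical intervals
  r <- minimal_common_region(ivs(c(10, 50), c(10, 50), c(10, 50)), min_support = 2)
  expect_equal(r$start, 10); expect_equal(r$end, 50); expect_equal(r$support, 3)
  # nested example: maximal support is the innermost interval
  r <- minimal_common_region(ivs(c(1, 100), c(50, 200), c(60, 80)), min_support = 2)
  expect_equal(r$start, 60); expect_equal(r$end, 80); expect_equal(r$support, 3)
  # two disjoint intervals cannot reach support 2
  r <- minimal_common_region(ivs(c(1, 10), c(100, 110)), min_support = 2)
  expect_equal(nrow(r), 0)

  # randomized agreement with the brute-force per-basepair counter
  set.seed(33)
  for (rep in 1:50) {
    sets <- lapply(seq_len(sample(2:5, 1)), function(i) {
      n <- sample.int(4, 1)
      s <- sort(sample.int(9999, 2 * n))
      data.frame(chrom = "chr1", start = s[seq(1, 2 * n, 2)],
                 end = s[seq(2, 2 * n, 2)])
    })
    got <- minimal_common_region(sets, min_support = 2)
    want <- oracle_mcr(sets, min_support = 2)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$support, want$support)
    }
  }
})

test_that("CN-event gene ranking deduplicates per patient per group", {
  calls <- rbind(
    data.frame(gene = "PARP1", category = "Amplification", patient_id = "P01",
               group = "recurrent"),
    data.frame(gene = "PARP1", category = "Amplification", patient_id = "P01",
               group = "recurrent"),
    data.frame(gene = "PARP1", category = "Gain", patient_id = "P01",
               group = "recurrent"),
    data.frame(gene = "PARP1", category = "Gain", patient_id = "P02",
               group = "recurrent"),
    data.frame(gene = "MYC", category = "Amplification", patient_id = "P01",
               group = "recurrent"),
    data.frame(gene = "MYC", category = "Amplification", patient_id = "P02",
               group = "recurrent"))
  r <- rank_genes_by_cn_event(calls, "gain_or_amp", "recurrent")
  # 3 recurrent-group events in P01 count once; ties broken lexicographically
  expect_equal(r$score, c(2, 2))
  expect_equal(r$gene, c("MYC", "PARP1"))
  expect_equal(nrow(rank_genes_by_cn_event(calls[0, ], "gain_or_amp",
                                           "recurrent")), 0)
  expect_error(rank_genes_by_cn_event(calls, "gain_or_amp", "relapse"),
               "unknown group")
})
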