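test_that("somatic filter applies the four rules with exact boundaries", {
  v <- rbind(
    mk_variant(pos = 1, alt_depth = 5, n_callers_pass = 1,
               pop_freq_max = 0.001),               # boundary: kept
    mk_variant(pos = 2, alt_depth = 4),             # depth below 5
    mk_variant(pos = 3, pop_freq_max = 0.01),       # >= 0.01 is common
    mk_variant(pos = 4, pop_freq_max = 0.0099),     # just under: kept
    mk_variant(pos = 5, exonic = FALSE),            # non-exonic
    mk_variant(pos = 6, n_callers_pass = 0),        # no passing caller
    mk_variant(pos = 7, pop_freq_max = NA))         # unknown: retained
  kept <- filter_somatic(v)
  expect_equal(kept$pos, c(1, 4, 7))
  removed <- attr(kept, "removed")
  expect_equal(removed$removed_by[match(c(2, 3, 5, 6), removed$pos)],
               c("alt_depth_below_5", "common_variant", "non_exonic",
                 "no_passing_caller"))
  # each exclusion attributed to exactly one rule
  expect_equal(nrow(kept) + nrow(removed), nrow(v))
  # idempotent
  again <- filter_somatic(kept)
  expect_equal(again$pos, kept$pos)
  expect_equal(nrow(attr(again, "removed")), 0)
})

test_that("LoF classification: frameshift, nonsense, or REVEL > 0.5 missense", {
  expect_true(classify_lof(mk_variant(effect = "nonsense")))
  expect_true(classify_lof(mk_variant(effect = "frameshift")))
  expect_true(classify_lof(mk_variant(effect = "missense", revel = 0.51)))
  # strict > 0.5: the boundary itself is excluded
  expect_false(classify_lof(mk_variant(effect = "missense", revel = 0.5)))
  # unknown REVEL on missense is not LoF
  expect_false(classify_lof(mk_variant(effect = "missense", revel = NA)))
  expect_false(classify_lof(mk_variant(effect = "synonymous")))
  expect_false(classify_lof(mk_variant(effect = "splice", revel = 0.9)))
})

test_that("GoF requires COSMIC membership, Tier-1 oncogene, and type match", {
  lk <- load_synthetic_lookups()
  akt1 <- mk_variant(chrom = "chr14", pos = 105246551, ref = "T", alt = "C",
                     gene = "AKT1", effect = "missense", revel = 0.2)
  expect_true(classify_gof(akt1, lk$cosmic_keys, lk$cgc))

  # same key but gene not Tier-1 -> false
  not_tier1 <- akt1; not_tier1$gene <- "TP53"
  expect_false(classify_gof(not_tier1, lk$cosmic_keys, lk$cgc))

  # key absent from the membership set -> false
  off_key <- akt1; off_key$pos <- 1
  expect_false(classify_gof(off_key, lk$cosmic_keys, lk$cgc))

  # a LoF variant can never be GoF, even in an oncogene
  lof_onco <- akt1; lof_onco$effect <- "nonsense"
  expect_false(classify_gof(lof_onco, lk$cosmic_keys, lk$cgc))

  # effect must match the gene's oncogenic mutation type
  wrong_type <- akt1; wrong_type$effect <- "splice"
  expect_false(classify_gof(wrong_type, lk$cosmic_keys, lk$cgc))

  expect_error(classify_gof(akt1, NULL, NULL), "requires local")
})

test_that("is_lof and is_gof are unsatisfiable together over all combinations", {
  lk <- load_synthetic_lookups()
  grid <- expand.grid(effect = c("frameshift", "nonsense", "missense",
                                 "synonymous", "splice", "other"),
                      revel = c(NA, 0.4, 0.51),
                      in_cosmic = c(TRUE, FALSE),
                      gene = c("AKT1", "TP53", "UNLISTED"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    v <- mk_variant(chrom = "chr14", pos = 105246551, ref = "T", alt = "C",
                    gene = g$gene, effect = g$effect, revel = g$revel)
    keys <- if (g$in_cosmic) variant_key(v) else character(0)
    fc <- classify_functional(v, keys, lk$cgc)
    expect_false(fc$is_lof && fc$is_gof)
  }
})

test_that("LoF prevalence ranking counts each patient once per group", {
  calls <- rbind(
    cbind(mk_variant(sample_id = "P01-R1", pos = 10, effect = "nonsense"),
          patient_id = "P01", group = "recurrent"),
    cbind(mk_variant(sample_id = "P01-R2", pos = 20, effect = "frameshift"),
          patient_id = "P01", group = "recurrent"),
    cbind(mk_variant(sample_id = "P01-R3", pos = 30, effect = "nonsense"),
          patient_id = "P01", group = "recurrent"),
    cbind(mk_variant(sample_id = "P02-R1", pos = 40, effect = "nonsense"),
          patient_id = "P02", group = "recurrent"),
    cbind(mk_variant(sample_id = "P02-R1", gene = "NF1", pos = 50,
                     effect = "synonymous"),
          patient_id = "P02", group = "recurrent"))
  calls$is_lof <- classify_lof(calls)
  # 3 distinct TP53 LoF mutations across one patient's recurrences count once
  r <- rank_genes_by_lof_prevalence(calls, "recurrent")
  expect_equal(r$gene, "TP53")
  expect_equal(r$score, 2)
  # synonymous NF1 never enters; empty group -> empty ranking
  expect_equal(nrow(rank_genes_by_lof_prevalence(calls, "primary")), 0)
  # scores bounded by patient count and invariant to duplicating calls
  r2 <- rank_genes_by_lof_prevalence(rbind(calls, calls), "recurrent")
  expect_equal(r2, r)
  # rnk side effect
  tmp <- withr::local_tempfile(fileext = ".rnk")
  rank_genes_by_lof_prevalence(calls, "recurrent", rnk_path = tmp)
  expect_equal(readLines(tmp), "TP53\t2")
})

test_that("shared-variant report flags sharing at the AAF threshold", {
  v <- rbind(mk_variant(sample_id = "T0", pos = 100, aaf = 0.012),
             mk_variant(sample_id = "R1", pos = 100, aaf = 0.329),
             mk_variant(sample_id = "T0", pos = 200, aaf = 0.4),
             mk_variant(sample_id = "R1", pos = 200, aaf = 0.41))
  # the low-AAF primary call drops below the default 5% threshold
  r5 <- shared_variant_report(v, aaf_threshold = 0.05)
  row <- r5[grepl(":100:", r5$key), ]
  expect_equal(row$status, "private:R1")
  expect_equal(row$aaf_T0, 0.012)
  # at a 1% threshold the same variant is shared
  r1 <- shared_variant_report(v, aaf_threshold = 0.01)
  expect_equal(r1[grepl(":100:", r1$key), ]$status, "shared")
  # identical AAFs across tumors are shared
  expect_equal(r5[grepl(":200:", r5$key), ]$status, "shared")
  # variants absent everywhere are not reported
  v2 <- rbind(v, mk_variant(sample_id = "T0", pos = 300, aaf = 0.001))
  expect_false(any(grepl(":300:", shared_variant_report(v2)$key)))
  expect_error(shared_variant_report(v[v$sample_id == "T0", ]), ">= 2 tumors")
})
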