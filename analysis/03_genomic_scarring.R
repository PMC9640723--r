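#!/usr/bin/env Rscript
# Genomic-scarring scores per tumor (NtAI, LST, HRD-LOH, HRD sum, arm-level
# aneuploidy, TMB) and paired primary-vs-recurrence Wilcoxon signed-rank
# tests with one randomly chosen recurrence per patient (seeded).
#
# Reads results/cohort/; writes results/tables/scar_scores.tsv and
# paired_tests.tsv.

library(lohscape)

cohort_dir <- "results/cohort"
metadata <- read_cohort_metadata(file.path(cohort_dir, "metadata.csv"))
annotation <- read_genome_annotation(file.path(cohort_dir,
                                               "genome_annotation.tsv"))
variants <- filter_somatic(read_variants(file.path(cohort_dir,
                                                   "variants.tsv")))
by_sample <- split(variants, variants$sample_id)

scores <- do.call(rbind, lapply(
  sort(list.files(file.path(cohort_dir, "segments"), full.names = TRUE)),
  function(f) {
    p <- read_segments(f)
    compute_scar_scores(p, annotation, scar_config(),
                        variants = by_sample[[p$sample_id]],
                        capture_size_mbp = 50)
  }))

cat("Score distribution across", nrow(scores), "tumors:\n")
print(summary(scores[, c("ntai", "lst", "hrd_loh", "hrd_sum", "aneuploidy",
                         "tmb")]))

paired <- compare_paired_scores(scores, metadata, seed = 42)
cat("\nPaired primary vs recurrence (one random recurrence per patient,",
    nrow(paired$pairs), "pairs):\n")
print(paired$tests)

write_results(list(scar_scores = scores, paired_tests = paired$tests),
              "results/tables")
cat("Wrote results/tables/scar_scores.tsv and paired_tests.tsv\n")
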