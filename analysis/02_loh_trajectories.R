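#!/usr/bin/env Rscript
# Allele-specific LOH at the germline BRCA1/2 locus, per tumor, and
# patient-level LOH trajectories across recurrences.
#
# Reads results/cohort/ (from 01_simulate_cohort.R); writes
# results/tables/loh_calls.tsv and loh_trajectories.tsv.

library(lohscape)

cohort_dir <- "results/cohort"
metadata <- read_cohort_metadata(file.path(cohort_dir, "metadata.csv"))
annotation <- read_genome_annotation(file.path(cohort_dir,
                                               "genome_annotation.tsv"))
profiles <- list()
for (f in sort(list.files(file.path(cohort_dir, "segments"),
                          full.names = TRUE))) {
  p <- read_segments(f)
  profiles[[p$sample_id]] <- p
}

loh <- cohort_loh_calls(profiles, metadata, annotation)
s <- summarize_loh(loh)

cat("Per-group LOH fractions at the germline locus:\n")
print(s$by_group)
cat(sprintf("Concordant primary/recurrence LOH status: %.0f%% of %d patients\n",
            100 * s$concordant_fraction, nrow(loh$trajectories)))
cat("Trajectories:\n")
print(table(loh$trajectories$label))

write_results(list(loh_calls = loh$calls,
                   loh_trajectories = loh$trajectories),
              "results/tables")
cat("Wrote results/tables/loh_calls.tsv and loh_trajectories.tsv\n")
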