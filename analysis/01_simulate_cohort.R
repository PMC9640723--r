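#!/usr/bin/env Rscript
# Generate the synthetic paired primary/recurrent cohort used by all
# downstream analysis steps, and report what was planted.
#
# Emits results/cohort/ (segments/, variants.tsv, metadata.csv,
# isoform_counts.tsv, survival.csv, genome_annotation.tsv, truth.json).

library(lohscape)

seed <- 42L
out <- "results/cohort"
cfg <- sim_config(seed = seed)
cohort <- generate_cohort(cfg, out_dir = out)

cat("Synthetic cohort written to", out, "\n")
cat(sprintf("  patients: %d  tumors: %d (%d primary / %d recurrent)\n",
            nrow(cohort$truth$patients), nrow(cohort$metadata),
            sum(cohort$metadata$group == "primary"),
            sum(cohort$metadata$group == "recurrent")))
cat(sprintf("  planted LOH in primaries: %d/%d\n",
            sum(cohort$truth$samples$loh[cohort$truth$samples$group == "primary"]),
            sum(cohort$truth$samples$group == "primary")))
cat("  trajectory labels planted:\n")
print(table(cohort$truth$patients$trajectory))
cat(sprintf("  somatic variants: %d  isoform samples: %d (incl. %d normals)\n",
            nrow(cohort$variants), nrow(cohort$isoforms),
            sum(cohort$isoforms$group == "normal")))
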