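#!/usr/bin/env Rscript
# Somatic-variant filtering, LoF/GoF classification, per-patient-deduplicated
# LoF prevalence ranking (GSEA Preranked input), and a shared-variant report
# for one multi-tumor patient.
#
# Reads results/cohort/; writes results/tables/filtered_variants.tsv,
# lof_ranking_*.tsv, shared_variants_example.tsv and results/rnk/lof_*.rnk.

library(lohscape)

cohort_dir <- "results/cohort"
metadata <- read_cohort_metadata(file.path(cohort_dir, "metadata.csv"))
variants <- read_variants(file.path(cohort_dir, "variants.tsv"))

kept <- filter_somatic(variants)
removed <- attr(kept, "removed")
cat(sprintf("Filter: %d/%d variants kept", nrow(kept), nrow(variants)))
if (nrow(removed)) {
  cat(" (removed by rule: ",
      paste(names(table(removed$removed_by)), table(removed$removed_by),
            collapse = ", "), ")")
}
cat("\n")

lookups <- load_synthetic_lookups()
calls <- classify_functional(kept, lookups$cosmic_keys, lookups$cgc)
calls$patient_id <- metadata$patient_id[match(calls$sample_id,
                                              metadata$sample_id)]
calls$group <- metadata$group[match(calls$sample_id, metadata$sample_id)]
cat(sprintf("LoF calls: %d  GoF calls: %d\n", sum(calls$is_lof),
            sum(calls$is_gof)))

dir.create("results/rnk", recursive = TRUE, showWarnings = FALSE)
tables <- list(filtered_variants = calls)
for (grp in c("primary", "recurrent")) {
  ranked <- rank_genes_by_lof_prevalence(
    calls, grp, rnk_path = file.path("results/rnk", paste0("lof_", grp, ".rnk")))
  tables[[paste0("lof_ranking_", grp)]] <- ranked
  cat(sprintf("Top LoF genes (%s): %s\n", grp,
              paste(utils::head(ranked$gene, 5), collapse = ", ")))
}

# shared-variant matrix for the patient with the most tumors
counts <- table(metadata$patient_id)
pid <- names(counts)[which.max(counts)]
pv <- calls[calls$patient_id == pid, ]
rep <- shared_variant_report(pv, aaf_threshold = 0.05)
cat(sprintf("Patient %s (%d tumors): %d variants, %d shared at AAF >= 5%%\n",
            pid, counts[[pid]], nrow(rep), sum(rep$status == "shared")))
tables$shared_variants_example <- rep

write_results(tables, "results/tables")
cat("Wrote results/tables/filtered_variants.tsv and rankings\n")
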