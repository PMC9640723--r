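# lohscape

Analysis toolkit for matched primary and recurrent tumors from germline
*BRCA1/2* mutation carriers. Tumors in these patients typically lose the
wild-type allele (allele-specific loss of heterozygosity, LOH), become
homologous-recombination (HR) deficient, and accumulate characteristic
genomic scars; whether that state persists at recurrence — or reverts under
therapeutic pressure — determines whether HR-directed therapy (platinum,
PARP inhibition) still has a target. lohscape implements the full analysis
stack for such cohorts, plus a deterministic synthetic-cohort generator with
ground truth so every stage is testable without protected patient data.

## What it computes

* **Allele-specific LOH** at the pathogenic germline locus: a segment is LOH
  iff it retains zero B (minor) alleles; a tumor is LOH iff the segment
  containing the germline position is LOH. Patient-level trajectory labels
  across recurrences: `concordant_LOH`, `concordant_nonLOH`,
  `nonLOH_to_LOH`, `LOH_to_nonLOH`, `mixed`. Somatic second hits:
  LoF variant in the germline gene at AAF ≥ 0.25.
* **Genomic-scarring scores** per tumor:
  NtAI (telomeric allelic imbalance: major ≠ minor, reaching a chromosome
  end, not crossing the centromere), LST (breakpoints between ≥ 10 Mb
  segments after 3 Mb smoothing), HRD-LOH (sub-chromosomal LOH > 15 Mb),
  HRD sum = NtAI + LST + HRD-LOH, arm-level aneuploidy (≥ 80% of an arm away
  from rounded ploidy), and TMB = (exonic nonsynonymous SNVs + indels) /
  capture Mbp. Paired primary/recurrence Wilcoxon signed-rank tests with one
  seeded random recurrence per patient.
* **Copy number**: binning (0 Deletion / 1 Loss / 2–3 Neutral / 4–5 Gain /
  ≥ 6 Amplification), gene-level min-CN annotation (> 50% coverage for
  deletions, 100% for amplifications), 50% reciprocal-overlap shared/private
  segment comparison with basepair Jaccard, minimal common regions, and
  per-patient-deduplicated gene rankings (GSEA Preranked `.rnk` output).
* **Somatic variants**: filter (exonic ∧ ≥ 1 passing caller ∧ alt depth ≥ 5
  ∧ PopFreqMax < 0.01), LoF (frameshift / nonsense / missense REVEL > 0.5)
  and GoF (COSMIC-documented, CGC Tier-1 oncogene, matching oncogenic type)
  classification, LoF prevalence rankings, shared-variant matrices.
* **Isoform usage and survival**: two-isoform fractions and dominance
  (mutual exclusivity at IF < 0.2), Mantel–Haenszel trend test with
  continuity correction, isoform-switch detection (|dIF| ≥ 0.1 and BH
  q < 0.05), Cox proportional hazards (Efron ties) and Kaplan–Meier medians
  with log-log CIs for short-isoform exposure.

## Worked example

```r
library(lohscape)

cohort <- generate_cohort(sim_config(seed = 42), out_dir = "results/cohort")
loh <- cohort_loh_calls(cohort$profiles, cohort$metadata, cohort$annotation)
summarize_loh(loh)$by_group
#>       group  n n_loh  fraction
#> 1   primary 27    20 0.7407407
#> 2 recurrent 37    26 0.7027027

table(loh$trajectories$label)
#>    concordant_LOH concordant_nonLOH     LOH_to_nonLOH     nonLOH_to_LOH
#>                19                 6                 1                 1

fit_cox(cohort$survival, covariates = "exposure")
#>           term     coef        se       hr ci_lower ci_upper    p_value
#> 1 exposureTRUE 1.120426 0.5105916 3.066161 1.127121 8.341021 0.02820891
```

20 of 27 primaries (74%) and 26 of 37 recurrences (70%) show LOH at their
germline locus; 25 of 27 patients keep a concordant LOH status across
recurrence, one acquires LOH and one reverts. Patients whose tumors express
the short isoform have roughly 3-fold higher death hazard — the generator's
planted hazard ratio is 2.5, and the 95% CI (1.13–8.34) covers it.

The `analysis/` directory holds the same workflow as numbered drivers
(`01_simulate_cohort.R` … `06_isoform_survival.R`), each a thin script over
the package functions that prints what it found and writes its tables under
`results/tables/`.

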