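Package: lohscape
Title: Allele-Specific LOH, Genomic Scarring, and Isoform-Survival Analysis of
    Paired Primary/Recurrent BRCA1/2 Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for paired primary and recurrent tumors from
    germline BRCA1/2 mutation carriers. Calls allele-specific loss of
    heterozygosity (LOH) at the pathogenic germline locus from allele-specific
    copy-number segments, classifies patient-level LOH trajectories across
    recurrences, computes genomic-scarring scores (NtAI, LST, HRD-LOH,
    aneuploidy, tumor mutational burden), bins and annotates gene-level copy
    number with reciprocal-overlap/Jaccard segment-set comparison and
    minimal-common-region extraction, filters somatic variants and classifies
    loss-of-function/gain-of-function mutations with per-patient-deduplicated
    prevalence ranking, quantifies two-isoform BRCA2 usage with a
    Mantel-Haenszel trend test, and relates isoform exposure to overall
    survival via Cox and Kaplan-Meier models. Includes a fully deterministic
    synthetic-cohort generator with ground truth so every stage is testable
    without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    rtracklayer,
    optparse
Config/testthat/edition: 3
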