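---
title: "Paired primary/recurrent BRCA1/2 tumor analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired primary/recurrent BRCA1/2 tumor analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohscape)
```

## The scientific problem

Tumors arising in carriers of pathogenic germline *BRCA1/2* variants usually
inactivate the remaining wild-type allele — most often by copy-number loss of
heterozygosity (LOH) — which leaves them deficient in homologous
recombination (HR) and sensitive to platinum agents and PARP inhibitors.
Whether that deficiency persists when a tumor recurs after therapy is a
clinically decisive question: a recurrence that has reverted to the
heterozygous state (or grew out from a nonLOH subclone) may no longer respond
to HR-directed therapy. lohscape implements the analysis stack for a cohort
of matched primary and recurrent breast/ovarian tumors from *BRCA1/2*
carriers: allele-specific LOH calling at the germline locus, patient-level
LOH trajectories, genomic-scarring scores, gene-level copy-number analysis,
somatic-variant filtering and functional classification, and two-isoform
*BRCA2* usage with survival modeling.

## Allele-specific LOH and trajectories

Input is an allele-specific copy-number segmentation per tumor (Sequenza-like:
total, major/A and minor/B allele copies per segment, with purity and ploidy
estimates). A segment has undergone LOH exactly when it retains zero B
alleles; a tumor is called LOH when the segment containing the patient's
pathogenic germline position is LOH. Exact point containment is used — we
found no ground for a padding window, and segments are non-overlapping so
containment is unique. A locus not covered by any segment yields an
*indeterminate* call; indeterminate calls are excluded from all downstream
comparisons and can never flip a patient's trajectory label (absence of
evidence). A homozygous deletion at the locus (0 major / 0 minor) also has
zero B alleles and is classified LOH, with a separate flag so users can audit
this rare corner — the choice is a package design decision, not an inference
from the source cohorts this workflow emulates.

Patients with at least two evaluable tumors receive a trajectory label:
`concordant_LOH` / `concordant_nonLOH`, `nonLOH_to_LOH` (LOH acquired on
recurrence), `LOH_to_nonLOH` (reversal), or `mixed` when determinate
recurrences disagree among themselves (a patient whose tumors run
LOH → nonLOH → LOH is `mixed`, not a reversal — the category exists
precisely because multi-recurrence patients can show both directions).

A second, mutation-level route to biallelic loss is checked with
`detect_biallelic_somatic()`: a loss-of-function somatic variant in the
germline-mutant gene at alternative allele fraction (AAF) ≥ 0.25, a cutoff
reflecting whether the second hit is present in enough of the tumor to
constitute loss of the wild-type allele.

## Genomic-scarring scores

Three HR-deficiency scar components are counted per tumor from the same
segments; their thresholds are not universal constants in the field, so all
of them live in `scar_config()` and are echoed into every output:

* **HRD-LOH** — LOH segments longer than 15 Mb but shorter than the whole
  chromosome (default `hrd_loh_min_len = 15e6`). Whole-chromosome LOH
  reflects ploidy change, not scarring.
* **LST** — breakpoints between adjacent segments of ≥ 10 Mb after smoothing
  away segments < 3 Mb (`lst_min_segment`, `lst_smooth_below`). Smoothing
  merges same-state segments separated by gaps below the 3 Mb window
  *before* removal, so chains of small same-state pieces can coalesce; a
  counted breakpoint additionally requires the inter-segment gap to be below
  the window. The merge-before-remove order matters and is pinned down by a
  brute-force enumeration oracle in the test suite.
* **NtAI** — allelic-imbalance segments (major ≠ minor) of ≥ 1 Mb that reach
  a chromosome end within `telomere_tolerance` (10 kb) and do not cross the
  centromere. "Crossing" means spanning the full centromere interval; a
  segment that merely touches centromeric sequence while staying on one arm
  still counts, which is the behaviour that matters on real segmentations
  where centromeres are unmappable gaps.

The combined HRD score is the plain sum of the three components — the
workflow treats "combined" literally; no weighting is applied. The
**aneuploidy score** counts chromosome arms in which ≥ 80% of the arm length
has total copy number different from the sample's *rounded* ploidy; the 80%
rule and rounding are package design decisions (the score has no canonical
published definition at arm level for this purpose). **TMB** is the exact
quotient of filtered exonic nonsynonymous SNVs + indels over the capture
size in Mbp (default 50 Mbp, configurable).

Paired primary-vs-recurrence comparisons use a two-sided Wilcoxon
signed-rank test; for patients with multiple recurrences one recurrence is
chosen at random under a recorded seed, so every report is reproducible.
Zero differences are handled by the Pratt method (zeros are ranked, then
dropped from the signed sum), with the exact distribution for n < 20
zero-free untied pairs and a continuity-corrected normal approximation (with
tie/zero variance corrections) otherwise. All differences zero gives p = 1.

## Copy-number binning and segment-set comparison

Total copy number is binned as 0 = Deletion, 1 = Loss, 2–3 = Neutral,
4–5 = Gain, ≥ 6 = Amplification. A gene's copy number is the minimum over
segments intersecting its locus; a gene qualifies *deleted* when > 50% of
the locus is covered by Deletion-binned segments and *amplified* only when
100% is covered by Amplification-binned segments. Uncovered gene portions
count toward neither fraction, and the total covered fraction is reported so
poorly covered genes can be filtered — min-CN over covered parts only is a
deliberate choice documented here because the alternative (treating gaps as
CN 0) would manufacture deletions from missing data.

Two segment sets (e.g. significant amplifications in primary vs recurrent
tumors) are compared with 50% *reciprocal* overlap: a pair is shared when
the intersection is at least half of each interval's own length. Pairing is
greedy by intersection length with deterministic tie-breaks, and one-to-one:
a segment can be shared with at most one partner. The Jaccard index is
computed on basepairs (BEDtools convention) — total shared-pair intersection
over the union of all intervals in both sets — rather than on segment
counts. The minimal common region across samples is a breakpoint sweep:
elementary intervals between all input breakpoints are scored by the number
of distinct supporting samples, and the leftmost maximal-support run is
returned. Gene prevalence rankings count a gene at most once per patient per
tumor group, with lexicographic tie-breaks so `.rnk` files are byte-stable.

## Somatic-variant filtering and classification

The filter keeps a variant iff it is exonic, called and passed by ≥ 1
caller, has alternative-allele depth ≥ 5 reads, and has maximum population
frequency < 0.01. Each removal is attributed to exactly one rule, checked in
a fixed order, and the removed set is returned alongside the kept set.
Unknown population frequency retains the variant (treated as rare); unknown
REVEL on a missense variant makes it non-LoF — both are explicit sentinel
decisions, never silent defaults. LoF = frameshift ∨ nonsense ∨ (missense
with REVEL strictly > 0.5). GoF = not LoF ∧ documented in a local
COSMIC-style membership table ∧ Tier-1 oncogene per a local Cancer Gene
Census-style table ∧ effect matching the gene's recorded oncogenic type.
The package ships tiny *synthetic* stand-ins for those two lookup tables
(licensing prevents redistribution of the real releases); their schemas
(`key` = `chrom:pos:ref:alt`; `gene`/`tier`/`oncogenic_effect`) let users
drop in full releases unchanged. No network access ever occurs.

## Isoform usage and survival

For a two-isoform gene (here the canonical long and an alternative short
*BRCA2* transcript), the isoform fraction IF is each isoform's expression
over the total. A sample is dominated by one isoform when the other's IF is
below `both_threshold = 0.2`; at or above it the call is `both`. The 0.2
default makes "mutually exclusive expression" tables computable at realistic
sequencing noise; it is logged with every output. Patient-level *exposure*
is short-isoform expression (`short` or `both`) in any tumor — monotone by
construction. The group trend (normal → primary → recurrent) is tested with
a Mantel–Haenszel chi-squared test with continuity correction (1 df),
authored in closed form with the standard (N−1) hypergeometric variance so a
single stratum is also accepted; with one stratum the statistic equals the
Yates-corrected Pearson chi-square times (N−1)/N exactly.

Isoform switching between groups is a deliberate simplification of
exon-level GLM machinery: dIF = difference in mean short-isoform fraction,
significance by two-sided rank-sum test on per-sample IF with
Benjamini–Hochberg correction across tested genes, and a switch flag
requiring both |dIF| ≥ 0.1 and q < 0.05. The effect-size gate prevents
flagging statistically crisp but biologically trivial shifts.

Survival uses Cox proportional hazards (partial likelihood, Efron tie
handling; CI = exp(coef ± 1.96·SE); Wald p) and Kaplan–Meier medians with
log-log CIs; open-ended medians/CIs are reported as NA rather than
extrapolated. Covariate specs are explicit — univariate exposure for breast,
exposure plus recurrent status for ovarian — never automatic stepwise
selection.

## The synthetic cohort generator

Real inputs for this kind of study are protected patient data, so the
package includes a first-class generator (`sim_config()`,
`generate_cohort()`) that emits every input format with full ground truth.
Its defaults are the study conditions: 27 patients (13 breast / 14 ovarian,
germline BRCA1:BRCA2 ≈ 19:8), most patients with a single recurrence (up to
five), P(LOH | primary) = 0.81, per-recurrence transition probabilities
0.15 (nonLOH→LOH) and 0.10 (LOH→nonLOH), purity uniform on [0.4, 0.9],
clonal variants shared within a patient at AAF ≈ purity/2 (s.d. 0.03),
short-isoform dominance increasing 0.10 → 0.35 → 0.55 from normal to
primary to recurrent, 97% mutual exclusivity, exponential survival with
baseline hazard ln(2)/120 per month, true hazard ratio 2.5 for short-isoform
exposure and ~20% independent exponential censoring. These were chosen once
from the cohort structure being emulated and are not tuned.

The central design idea is that **injected events must be unambiguous under
the documented scoring thresholds**, so scar recovery is an exact oracle
rather than a statistical one. The background genome is uniformly diploid
(1,1); every event is an island separated from all other covered sequence by
≥ 3.5 Mb of uncovered genome (larger than the 3 Mb smoothing window, so no
spurious LSTs) and ≥ 5 Mb from other events:

* NtAI event: 6 Mb telomeric (2,1) — below 10 Mb so it can never flank an
  LST breakpoint;
* HRD-LOH event: 20 Mb interstitial (2,0);
* LST event: adjacent 12 Mb (2,1) | 12 Mb (3,1), one internal qualifying
  breakpoint;
* whole-arm aneuploidy event: (2,2) — balanced, so it is neither AI nor LOH,
  and the uncovered centromere (≥ 4 Mb in the shipped annotations) prevents
  an LST across the arm boundary;
* the germline-locus window is always explicitly covered — a 10 Mb (1,0)
  island for LOH tumors (long enough to carry the call, short of the 15 Mb
  HRD-LOH threshold), an explicit diploid segment otherwise — so no scar
  island or gap can corrupt the planted LOH status.

The default genome is a reduced 3-chromosome, 200 Mb annotation (fast to
simulate and to test); an hg19-scale 22-autosome annotation with approximate
Mb-rounded centromeres is available for capacity-hungry runs such as
injecting up to 10 events of each class per sample. Random number streams
are per component (segments, variants, isoforms, survival), so changing one
configuration block does not perturb the others, and the whole cohort is
byte-identical under a fixed seed.

What the generator deliberately does **not** emulate: read-level data,
segmentation noise (integer allele-specific states are exact, so LOH calling
is noiseless by construction), subclonal architecture beyond clonal/private
variants, trinucleotide mutational-signature context, and realistic
linkage between scar burden and LOH status. Passing tests on synthetic
cohorts therefore demonstrate the correctness of the *scoring and
classification logic*, not robustness to segmentation error in real tumors —
the latter is bounded upstream by the segmenter, not by this package.

## Problem sizes and numerical choices

The test suite validates the interval logic against independent brute-force
enumerators on 1,000 random profiles, recovers injected scar triplets
exactly on 50 hg19-scale samples with counts in 0..10, classifies planted
trajectories of 200 patients perfectly, and checks Cox coverage (200
replicates at n = 500, true HR 2.5, coverage ≥ 93%) and null Wald-p
uniformity (500 replicates at n = 200, KS at α = 0.01). These sizes were
chosen as the smallest at which the corresponding statistical property is
sharp. Ties in all rankings break lexicographically; all internal
coordinates are 1-based inclusive with BED I/O as the only 0-based boundary;
chromosome names are normalized to `chr`-prefixed.

## Known limitations

* LOH calling consumes integer allele-specific states; it does not infer LOH
  from B-allele frequencies or read counts, and purity enters only the
  variant AAF model, not the copy-number states themselves.
* The real cohort's published survival analysis cannot be reproduced here
  without the per-patient supplementary source table, which derives from
  protected data; the survival machinery is therefore validated by
  simulation recovery instead.
* The GoF classification is only as good as the supplied lookup tables; the
  shipped synthetic stand-ins exist to exercise the rule logic, not to call
  real variants.
* Promoter hypermethylation, an alternative route to BRCA1 silencing, is
  out of scope (no methylation input exists in this workflow).
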