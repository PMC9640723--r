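#' Somatic variant filter
#'
#' Keeps a variant iff it is exonic, was called and passed filtering by at
#' least one caller, has alternative-allele read depth of at least 5 reads,
#' and its maximum population frequency is below 0.01 (variants with unknown
#' population frequency are retained — treated as rare). Each removed variant
#' is attributed to exactly one rule, checked in the fixed order
#' `non_exonic`, `no_passing_caller`, `alt_depth_below_5`, `common_variant`.
#'
#' @param variants variant data.frame (see [read_variants()]).
#' @param min_alt_depth minimum alternative-allele read depth (default 5).
#' @param max_pop_freq population-frequency cutoff; variants with
#'   `pop_freq_max >= max_pop_freq` are removed (default 0.01).
#' @return the kept variants; the removed ones, with a `removed_by` column,
#'   are attached as attribute `"removed"`.
#' @export
filter_somatic <- function(variants, min_alt_depth = 5, max_pop_freq = 0.01) {
  if (!nrow(variants)) {
    out <- variants
    attr(out, "removed") <- cbind(variants, removed_by = character(0))
    return(out)
  }
  reason <- rep(NA_character_, nrow(variants))
  reason[is.na(reason) & !variants$exonic] <- "non_exonic"
  reason[is.na(reason) & variants$n_callers_pass < 1] <- "no_passing_caller"
  reason[is.na(reason) & variants$alt_depth < min_alt_depth] <- "alt_depth_below_5"
  reason[is.na(reason) & !is.na(variants$pop_freq_max) &
           variants$pop_freq_max >= max_pop_freq] <- "common_variant"
  kept <- variants[is.na(reason), , drop = FALSE]
  removed <- variants[!is.na(reason), , drop = FALSE]
  removed$removed_by <- reason[!is.na(reason)]
  rownames(kept) <- rownames(removed) <- NULL
  attr(kept, "removed") <- removed
  kept
}

#' Loss-of-function classification
#'
#' A variant is LoF when it is (1) a frameshift mutation, (2) a nonsense
#' mutation, or (3) a missense SNV predicted pathogenic by REVEL score
#' strictly greater than 0.5. Missense variants with an unknown REVEL score
#' are not LoF (absence of evidence).
#'
#' @param variants variant data.frame.
#' @param revel_threshold REVEL cutoff (strict `>`, default 0.5).
#' @return logical vector.
#' @export
classify_lof <- function(variants, revel_threshold = 0.5) {
  variants$effect == "frameshift" |
    variants$effect == "nonsense" |
    (variants$effect == "missense" & !is.na(variants$revel) &
       variants$revel > revel_threshold)
}

#' Gain-of-function classification
#'
#' A variant is GoF when it meets all of: (1) it is not LoF; (2) its
#' `chrom:pos:ref:alt` key is documented in the supplied COSMIC-style
#' membership set; (3) its gene is a Tier-1 oncogene per the supplied Cancer
#' Gene Census table; and (4) its effect class matches the mutation type
#' recorded as oncogenic for that gene. Lookup tables are local files — the
#' package never performs network lookups; tiny synthetic stand-ins ship
#' under `inst/extdata/` and users substitute full releases with the same
#' schema.
#'
#' @param variants variant data.frame.
#' @param cosmic_keys character vector of documented `chrom:pos:ref:alt` keys
#'   (see [variant_key()]).
#' @param cgc data.frame with columns `gene`, `tier` (1 = Tier-1 oncogene)
#'   and `oncogenic_effect` (effect class, e.g. "missense").
#' @return logical vector.
#' @export
classify_gof <- function(variants, cosmic_keys, cgc) {
  if (missing(cosmic_keys) || missing(cgc) || is.null(cosmic_keys) || is.null(cgc)) {
    stop_lohscape("classify_gof requires local COSMIC membership and CGC tables")
  }
  if (!all(c("gene", "tier", "oncogenic_effect") %in% names(cgc))) {
    stop_lohscape("CGC table needs columns gene, tier, oncogenic_effect")
  }
  if (!nrow(variants)) return(logical(0))
  lof <- classify_lof(variants)
  in_cosmic <- variant_key(variants) %in% cosmic_keys
  idx <- match(variants$gene, cgc$gene)
  tier1 <- !is.na(idx) & cgc$tier[idx] == 1
  type_match <- !is.na(idx) & variants$effect == cgc$oncogenic_effect[idx]
  !lof & in_cosmic & tier1 & type_match
}

#' Functional classification of a variant table
#'
#' Adds `is_lof`, `is_gof` and a `rationale` naming the rule that fired.
#' `is_lof` and `is_gof` are mutually exclusive by construction (GoF rule 1).
#'
#' @inheritParams classify_gof
#' @return the input with `is_lof`, `is_gof`, `rationale` columns.
#' @export
classify_functional <- function(variants, cosmic_keys, cgc) {
  variants$is_lof <- classify_lof(variants)
  variants$is_gof <- classify_gof(variants, cosmic_keys, cgc)
  variants$rationale <- ifelse(
    variants$effect %in% c("frameshift", "nonsense") & variants$is_lof,
    paste0("lof:", variants$effect),
    ifelse(variants$is_lof, "lof:missense_revel>0.5",
           ifelse(variants$is_gof, "gof:cosmic+cgc_tier1+type_match", "none")))
  variants
}

#' Rank genes by LoF prevalence within a tumor group
#'
#' Score = number of distinct patients with at least one LoF call in the gene
#' within the group; a gene counts at most once per patient per tumor group
#' (so neither patients with many recurrences nor tumors accruing several
#' distinct LoF mutations in one gene skew the ranking). Descending order,
#' ties broken lexicographically by gene symbol for byte-stable .rnk output.
#'
#' @param calls variant data.frame with `is_lof`, `gene`, `patient_id`,
#'   `group` columns (see [classify_functional()]).
#' @param group `"primary"` or `"recurrent"`.
#' @param rnk_path optional path; when given, the ranking is also written as
#'   a GSEA Preranked .rnk file.
#' @return data.frame with `gene` and `score`.
#' @export
rank_genes_by_lof_prevalence <- function(calls, group, rnk_path = NULL) {
  if (!group %in% c("primary", "recurrent")) {
    stop_lohscape("unknown group label: ", group)
  }
  d <- calls[!is.na(calls$is_lof) & calls$is_lof & calls$group == group, ,
             drop = FALSE]
  if (!nrow(d)) {
    ranked <- data.frame(gene = character(), score = integer(),
                         stringsAsFactors = FALSE)
  } else {
    ranked <- aggregate(patient_id ~ gene, data = d,
                        FUN = function(p) length(unique(p)))
    names(ranked)[2] <- "score"
    ranked <- ranked[order(-ranked$score, ranked$gene), , drop = FALSE]
    rownames(ranked) <- NULL
  }
  if (!is.null(rnk_path)) write_rnk(ranked, rnk_path)
  ranked
}

#' Shared-variant report for one patient's tumors
#'
#' For every variant observed in at least one of the patient's tumors,
#' reports the AAF in each tumor and whether the variant is shared (present
#' at `aaf_threshold` or above in at least two tumors) or private to a single
#' tumor. Variants below threshold everywhere are dropped.
#'
#' @param variants variant data.frame covering >= 2 tumors of one patient
#'   (distinct `sample_id`s).
#' @param aaf_threshold presence threshold on AAF (default 0.05).
#' @return data.frame: `key`, `gene`, one `aaf_<sample>` column per tumor,
#'   `status` ("shared" or "private:<sample>").
#' @export
shared_variant_report <- function(variants, aaf_threshold = 0.05) {
  samples <- sort(unique(variants$sample_id))
  if (length(samples) < 2) {
    stop_lohscape("shared-variant report needs >= 2 tumors of one patient")
  }
  variants$key <- variant_key(variants)
  keys <- unique(variants[, c("key", "gene")])
  aaf_mat <- sapply(samples, function(s) {
    v <- variants[variants$sample_id == s, ]
    v$aaf[match(keys$key, v$key)]
  })
  aaf_mat <- matrix(aaf_mat, nrow = nrow(keys),
                    dimnames = list(NULL, paste0("aaf_", samples)))
  aaf_mat[is.na(aaf_mat)] <- 0
  present <- aaf_mat >= aaf_threshold
  n_present <- rowSums(present)
  keep <- n_present >= 1
  status <- ifelse(n_present >= 2, "shared",
                   paste0("private:", samples[apply(present, 1, which.max)]))
  out <- cbind(keys, as.data.frame(aaf_mat), status = status,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the synthetic COSMIC/CGC stand-in lookup tables
#'
#' Small plain-text stand-ins for the COSMIC variant catalogue and the Cancer
#' Gene Census Tier-1 oncogene table, shipped for tests and examples
#' (filenames are marked `synthetic`). Users substitute real releases with
#' the same columns.
#'
#' @return list with `cosmic_keys` (character) and `cgc` (data.frame).
#' @export
load_synthetic_lookups <- function() {
  cgc <- read.delim(system.file("extdata", "cgc_tier1_oncogenes.synthetic.tsv",
                                package = "lohscape"),
                    stringsAsFactors = FALSE)
  cosmic <- read.delim(system.file("extdata", "cosmic_variants.synthetic.tsv",
                                   package = "lohscape"),
                       stringsAsFactors = FALSE)
  list(cosmic_keys = cosmic$key, cgc = cgc)
}
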