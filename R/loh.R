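#' Zygosity of an allele-specific copy-number segment
#'
#' A segment has undergone loss of heterozygosity when zero B (minor) alleles
#' remain; at least one B allele means the segment is still heterozygous.
#' Homozygous deletions (0 major, 0 minor) carry zero B alleles and are
#' classified LOH; callers that care can detect them via `cn_total == 0`.
#'
#' @param cn_major,cn_minor major (A) and minor (B) allele copy numbers;
#'   vectorized.
#' @return character vector, `"LOH"` or `"heterozygous"`.
#' @export
segment_zygosity <- function(cn_major, cn_minor) {
  if (any(cn_minor > cn_major) || any(cn_minor < 0)) {
    stop_lohscape("need cn_major >= cn_minor >= 0")
  }
  ifelse(cn_minor == 0, "LOH", "heterozygous")
}

#' Call allele-specific LOH at the germline pathogenic locus
#'
#' A tumor is deemed LOH when the segment containing the patient's pathogenic
#' germline BRCA1/2 position has zero B alleles (i.e. the wild-type allele was
#' lost by copy number). Exact point containment is used; when no segment
#' covers the locus the call is indeterminate.
#'
#' @param profile a [segment_profile()].
#' @param locus list or data.frame row with `chrom` and `pos`.
#' @param annotation optional [genome_annotation()]; when given, a locus on a
#'   chromosome absent from the annotation is an error.
#' @return list of class `loh_call`: `sample_id`, `status` ("LOH", "nonLOH" or
#'   "indeterminate"), `homozygous_deletion` flag, the supporting `segment`
#'   (1-row data.frame or NULL) and the `locus`.
#' @export
call_brca_loh <- function(profile, locus, annotation = NULL) {
  stopifnot(inherits(profile, "segment_profile"))
  chrom <- normalize_chrom(as.character(locus$chrom))
  pos <- as.numeric(locus$pos)
  if (!is.null(annotation) && !chrom %in% names(annotation$chrom_lengths)) {
    stop_lohscape("locus chromosome ", chrom, " not in genome annotation")
  }
  seg <- profile$segments
  hit <- seg[seg$chrom == chrom & seg$start <= pos & seg$end >= pos, , drop = FALSE]
  if (nrow(hit) == 0) {
    status <- "indeterminate"
    hom_del <- FALSE
    supporting <- NULL
  } else {
    supporting <- hit[1, , drop = FALSE]
    status <- if (supporting$cn_minor == 0) "LOH" else "nonLOH"
    hom_del <- supporting$cn_total == 0
  }
  structure(list(sample_id = profile$sample_id, status = status,
                 homozygous_deletion = hom_del, segment = supporting,
                 locus = list(chrom = chrom, pos = pos)),
            class = "loh_call")
}

#' Classify a patient's LOH trajectory across timepoints
#'
#' Given per-sample LOH calls ordered by timepoint (timepoint 0 = primary),
#' labels the patient's evolution:
#' * `concordant_LOH` / `concordant_nonLOH` — all determinate calls agree;
#' * `nonLOH_to_LOH` — nonLOH primary with LOH recurrence(s) (LOH acquired);
#' * `LOH_to_nonLOH` — LOH primary with nonLOH recurrence(s) (LOH reversal);
#' * `mixed` — determinate recurrences disagree among themselves (e.g. an
#'   LOH primary followed by a nonLOH and then an LOH recurrence).
#'
#' Indeterminate calls are excluded from the comparison and can never flip a
#' label. If the primary itself is indeterminate the label is derived from the
#' recurrences alone (concordant if they agree, mixed otherwise).
#'
#' @param statuses character vector of per-sample calls
#'   ("LOH"/"nonLOH"/"indeterminate") ordered by timepoint.
#' @param timepoints integer timepoints (0 = primary); defaults to
#'   `seq_along(statuses) - 1`.
#' @param patient_id optional identifier carried into the result.
#' @return list of class `loh_trajectory` with `patient_id`, `label`, and the
#'   ordered `statuses`.
#' @export
classify_trajectory <- function(statuses,
                                timepoints = seq_along(statuses) - 1,
                                patient_id = NA_character_) {
  stopifnot(length(statuses) == length(timepoints))
  ord <- order(timepoints)
  statuses <- statuses[ord]
  timepoints <- timepoints[ord]
  if (sum(timepoints == 0) != 1) {
    stop_lohscape("need exactly one primary (timepoint 0); got ",
                  sum(timepoints == 0))
  }
  if (length(statuses) < 2) stop_lohscape("need >= 2 calls per patient")
  det <- statuses != "indeterminate"
  if (sum(det) < 2) stop_lohscape("insufficient evaluable tumors (",
                                  sum(det), " determinate call(s))")
  primary <- statuses[timepoints == 0]
  recs <- statuses[timepoints > 0]
  recs <- recs[recs != "indeterminate"]
  label <- if (primary == "indeterminate") {
    if (length(unique(recs)) == 1) paste0("concordant_", recs[1]) else "mixed"
  } else if (length(recs) == 0) {
    # primary determinate but all recurrences indeterminate: cannot happen
    # given >= 2 determinate calls include the primary and one recurrence
    paste0("concordant_", primary)
  } else if (all(recs == primary)) {
    paste0("concordant_", primary)
  } else if (length(unique(recs)) > 1) {
    "mixed"
  } else if (primary == "nonLOH") {
    "nonLOH_to_LOH"
  } else {
    "LOH_to_nonLOH"
  }
  structure(list(patient_id = patient_id, label = label,
                 statuses = statuses, timepoints = timepoints),
            class = "loh_trajectory")
}

#' Detect biallelic loss via a somatic second hit
#'
#' Checks whether any loss-of-function somatic variant in the germline-mutant
#' gene is present at an alternative allele fraction of at least
#' `aaf_threshold` (default 0.25) — i.e. in enough of the tumor to constitute
#' loss of the wild-type allele.
#'
#' @param variants variant data.frame (see [read_variants()]).
#' @param gene the germline-mutant gene symbol (e.g. "BRCA1").
#' @param aaf_threshold minimum AAF (default 0.25).
#' @return single logical.
#' @export
detect_biallelic_somatic <- function(variants, gene, aaf_threshold = 0.25) {
  if (!nrow(variants)) return(FALSE)
  v <- variants[variants$gene == gene, , drop = FALSE]
  if (!nrow(v)) return(FALSE)
  any(classify_lof(v) & v$aaf >= aaf_threshold)
}

#' Per-sample LOH calls and per-patient trajectories for a cohort
#'
#' Applies [call_brca_loh()] to every sample and [classify_trajectory()] to
#' every patient with at least two evaluable tumors.
#'
#' @param profiles named list of [segment_profile()]s (names = sample ids).
#' @param metadata cohort metadata (see [read_cohort_metadata()]).
#' @param annotation optional [genome_annotation()].
#' @return list with `calls` (data.frame: sample_id, patient_id, group,
#'   timepoint, status, homozygous_deletion) and `trajectories` (data.frame:
#'   patient_id, label, n_evaluable).
#' @export
cohort_loh_calls <- function(profiles, metadata, annotation = NULL) {
  metadata <- validate_cohort_metadata(metadata)
  calls <- do.call(rbind, lapply(seq_len(nrow(metadata)), function(i) {
    row <- metadata[i, ]
    prof <- profiles[[row$sample_id]]
    if (is.null(prof)) {
      return(data.frame(sample_id = row$sample_id, patient_id = row$patient_id,
                        group = row$group, timepoint = row$timepoint,
                        status = "indeterminate", homozygous_deletion = FALSE,
                        stringsAsFactors = FALSE))
    }
    call <- call_brca_loh(prof, list(chrom = row$germline_chrom,
                                     pos = row$germline_pos), annotation)
    data.frame(sample_id = row$sample_id, patient_id = row$patient_id,
               group = row$group, timepoint = row$timepoint,
               status = call$status,
               homozygous_deletion = call$homozygous_deletion,
               stringsAsFactors = FALSE)
  }))
  traj <- lapply(split(calls, calls$patient_id), function(d) {
    res <- tryCatch(
      classify_trajectory(d$status, d$timepoint, patient_id = d$patient_id[1]),
      lohscape_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(patient_id = res$patient_id, label = res$label,
               n_evaluable = sum(d$status != "indeterminate"),
               stringsAsFactors = FALSE)
  })
  traj <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
  if (is.null(traj)) {
    traj <- data.frame(patient_id = character(), label = character(),
                       n_evaluable = integer(), stringsAsFactors = FALSE)
  }
  rownames(calls) <- rownames(traj) <- NULL
  list(calls = calls, trajectories = traj)
}

#' Cohort LOH summary fractions
#'
#' Fraction of determinate tumors with LOH per group, and the fraction of
#' classifiable patients with concordant primary/recurrence LOH status.
#'
#' @param loh result of [cohort_loh_calls()].
#' @return list with `by_group` (data.frame: group, n, n_loh, fraction) and
#'   `concordant_fraction`.
#' @export
summarize_loh <- function(loh) {
  det <- loh$calls[loh$calls$status != "indeterminate", ]
  by_group <- do.call(rbind, lapply(split(det, det$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               n_loh = sum(d$status == "LOH"),
               fraction = mean(d$status == "LOH"), stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  conc <- if (nrow(loh$trajectories)) {
    mean(grepl("^concordant_", loh$trajectories$label))
  } else {
    NA_real_
  }
  list(by_group = by_group, concordant_fraction = conc)
}
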