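#' Thresholds for genomic-scarring scores
#'
#' The three homologous-recombination-deficiency (HRD) components are counted
#' from allele-specific segments under length/position thresholds adopted from
#' the literature each component originates in:
#' * HRD-LOH: LOH segments longer than `hrd_loh_min_len` (15 Mb) but shorter
#'   than the whole chromosome;
#' * LST (large-scale state transitions): breakpoints between adjacent
#'   segments of at least `lst_min_segment` (10 Mb) after smoothing away
#'   segments shorter than `lst_smooth_below` (3 Mb); the inter-segment gap at
#'   a counted breakpoint must be below `lst_smooth_below`;
#' * NtAI (telomeric allelic imbalance): allelic-imbalance segments of at
#'   least `ntai_min_len` (1 Mb) that reach a chromosome end within
#'   `telomere_tolerance` (10 kb) without crossing the centromere.
#'
#' All thresholds are in bp and configurable; every scoring function echoes
#' the configuration it applied.
#'
#' @param hrd_loh_min_len,lst_min_segment,lst_smooth_below,ntai_min_len,telomere_tolerance
#'   thresholds in bp.
#' @return list of class `scar_config`.
#' @export
scar_config <- function(hrd_loh_min_len = 15e6, lst_min_segment = 10e6,
                        lst_smooth_below = 3e6, ntai_min_len = 1e6,
                        telomere_tolerance = 1e4) {
  if (any(c(hrd_loh_min_len, lst_min_segment, lst_smooth_below,
            ntai_min_len) <= 0) || telomere_tolerance < 0) {
    stop_lohscape("scar thresholds must be positive")
  }
  if (lst_smooth_below >= lst_min_segment) {
    stop_lohscape("lst_smooth_below must be < lst_min_segment")
  }
  structure(list(hrd_loh_min_len = hrd_loh_min_len,
                 lst_min_segment = lst_min_segment,
                 lst_smooth_below = lst_smooth_below,
                 ntai_min_len = ntai_min_len,
                 telomere_tolerance = telomere_tolerance),
            class = "scar_config")
}

#' HRD-LOH: count of long sub-chromosomal LOH segments
#'
#' Counts segments with zero minor-allele copies whose length exceeds
#' `config$hrd_loh_min_len` but is less than the full chromosome length
#' (whole-chromosome LOH reflects ploidy changes, not scarring).
#'
#' @param profile a [segment_profile()].
#' @param annotation a [genome_annotation()] supplying chromosome lengths.
#' @param config a [scar_config()].
#' @return integer count.
#' @export
compute_hrd_loh <- function(profile, annotation, config = scar_config()) {
  seg <- profile$segments
  if (!nrow(seg)) return(0L)
  len <- segment_lengths(seg)
  chrom_len <- annotation$chrom_lengths[seg$chrom]
  if (anyNA(chrom_len)) {
    stop_lohscape("chromosome ", seg$chrom[which(is.na(chrom_len))[1]],
                  " missing from genome annotation")
  }
  sum(seg$cn_minor == 0 & len > config$hrd_loh_min_len & len < chrom_len)
}

#' NtAI: count of telomeric allelic-imbalance segments
#'
#' Counts segments with unequal major/minor allele copies that reach a
#' chromosome end (within `telomere_tolerance`), do not cross the centromere
#' (i.e. do not span the full centromere interval), are shorter than the whole
#' chromosome, and are at least `ntai_min_len` long.
#'
#' @inheritParams compute_hrd_loh
#' @return integer count.
#' @export
compute_ntai <- function(profile, annotation, config = scar_config()) {
  seg <- profile$segments
  if (!nrow(seg)) return(0L)
  chrom_len <- annotation$chrom_lengths[seg$chrom]
  if (anyNA(chrom_len)) {
    stop_lohscape("chromosome ", seg$chrom[which(is.na(chrom_len))[1]],
                  " missing from genome annotation")
  }
  cen <- annotation$centromere[match(seg$chrom, annotation$centromere$chrom), ]
  len <- segment_lengths(seg)
  ai <- seg$cn_major != seg$cn_minor
  telomeric <- seg$start <= 1 + config$telomere_tolerance |
    seg$end >= chrom_len - config$telomere_tolerance
  crosses_cen <- seg$start < cen$start & seg$end > cen$end
  sum(ai & telomeric & !crosses_cen & len < chrom_len &
        len >= config$ntai_min_len)
}

# LST preprocessing: merge same-state segments separated by less than the
# smoothing window (bridging), then remove sub-window segments and re-merge
# flanks that come into range; iterate to a fixed point. Merging runs before
# removal so chains of small same-state pieces can coalesce into a segment
# large enough to survive.
smooth_segments_lst <- function(seg, config) {
  repeat {
    merged <- seg[1, , drop = FALSE]
    for (i in seq_len(nrow(seg))[-1]) {
      last <- nrow(merged)
      gap <- seg$start[i] - merged$end[last] - 1
      same_state <- seg$chrom[i] == merged$chrom[last] &&
        seg$cn_major[i] == merged$cn_major[last] &&
        seg$cn_minor[i] == merged$cn_minor[last]
      if (same_state && gap < config$lst_smooth_below) {
        merged$end[last] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, , drop = FALSE])
      }
    }
    keep <- segment_lengths(merged) >= config$lst_smooth_below
    seg2 <- merged[keep, , drop = FALSE]
    if (!nrow(seg2)) return(seg2)
    if (identical(seg2, seg)) break
    seg <- seg2
  }
  rownames(seg) <- NULL
  seg
}

#' LST: count of large-scale state transitions
#'
#' After merging adjacent same-state segments and smoothing away segments
#' shorter than `config$lst_smooth_below`, counts breakpoints at which both
#' flanking segments are at least `config$lst_min_segment` long, their
#' allele-specific states differ, and the inter-segment gap is below the
#' smoothing window.
#'
#' @param profile a [segment_profile()].
#' @param config a [scar_config()].
#' @return integer count.
#' @export
compute_lst <- function(profile, config = scar_config()) {
  seg <- profile$segments
  if (nrow(seg) < 2) return(0L)
  count <- 0L
  for (ch in unique(seg$chrom)) {
    s <- smooth_segments_lst(seg[seg$chrom == ch, , drop = FALSE], config)
    if (nrow(s) < 2) next
    len <- segment_lengths(s)
    for (i in seq_len(nrow(s) - 1)) {
      gap <- s$start[i + 1] - s$end[i] - 1
      state_change <- s$cn_major[i] != s$cn_major[i + 1] ||
        s$cn_minor[i] != s$cn_minor[i + 1]
      if (state_change && gap < config$lst_smooth_below &&
          len[i] >= config$lst_min_segment &&
          len[i + 1] >= config$lst_min_segment) {
        count <- count + 1L
      }
    }
  }
  count
}

#' Arm-level aneuploidy score
#'
#' Number of chromosome arms in which at least `min_fraction` (default 80%)
#' of the arm length is covered by segments whose total copy number differs
#' from the sample's rounded ploidy.
#'
#' @param profile a [segment_profile()].
#' @param annotation a [genome_annotation()].
#' @param min_fraction minimum altered fraction of the arm (default 0.8).
#' @return integer count of altered arms.
#' @export
compute_aneuploidy <- function(profile, annotation, min_fraction = 0.8) {
  seg <- profile$segments
  base_cn <- round(profile$ploidy)
  altered <- seg[seg$cn_total != base_cn, , drop = FALSE]
  count <- 0L
  for (i in seq_len(nrow(annotation$arms))) {
    arm <- annotation$arms[i, ]
    s <- altered[altered$chrom == arm$chrom, , drop = FALSE]
    if (!nrow(s)) next
    ov <- pmin(s$end, arm$end) - pmax(s$start, arm$start) + 1
    covered <- sum(pmax(ov, 0))
    if (covered >= min_fraction * (arm$end - arm$start + 1)) count <- count + 1L
  }
  count
}

#' Tumor mutational burden
#'
#' `TMB = (number of somatic exonic nonsynonymous SNVs + indels) /
#' capture size in Mbp`. The numerator should count variants surviving the
#' somatic filter (see [filter_somatic()]) whose effect is not synonymous.
#'
#' @param n_nonsyn count of filtered exonic nonsynonymous SNVs + indels.
#' @param capture_size_mbp exome capture size in Mbp (> 0).
#' @return mutations per Mbp.
#' @export
compute_tmb <- function(n_nonsyn, capture_size_mbp) {
  if (capture_size_mbp <= 0) stop_lohscape("capture size must be > 0 Mbp")
  if (n_nonsyn < 0) stop_lohscape("variant count must be >= 0")
  n_nonsyn / capture_size_mbp
}

#' All scarring scores for one sample
#'
#' @param profile a [segment_profile()].
#' @param annotation a [genome_annotation()].
#' @param config a [scar_config()].
#' @param variants optional filtered variant data.frame for this sample (used
#'   for TMB); `NULL` leaves TMB as NA.
#' @param capture_size_mbp exome capture size in Mbp.
#' @return data.frame (1 row) with sample_id, ntai, lst, hrd_loh, hrd_sum,
#'   aneuploidy, tmb.
#' @export
compute_scar_scores <- function(profile, annotation, config = scar_config(),
                                variants = NULL, capture_size_mbp = 50) {
  ntai <- compute_ntai(profile, annotation, config)
  lst <- compute_lst(profile, config)
  hrd_loh <- compute_hrd_loh(profile, annotation, config)
  tmb <- if (is.null(variants)) {
    NA_real_
  } else {
    compute_tmb(sum(variants$effect != "synonymous"), capture_size_mbp)
  }
  data.frame(sample_id = profile$sample_id, ntai = ntai, lst = lst,
             hrd_loh = hrd_loh, hrd_sum = ntai + lst + hrd_loh,
             aneuploidy = compute_aneuploidy(profile, annotation),
             tmb = tmb, stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired two-sided signed-rank test. Zero differences are handled by the
#' Pratt method: zeros participate in the ranking of absolute differences and
#' are then discarded from the signed sum. With no zeros and no ties and
#' n < 20 the exact distribution is used (via [stats::wilcox.test()]);
#' otherwise a normal approximation with continuity correction and tie/zero
#' variance corrections. All differences zero gives p = 1.
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V, sum of positive signed ranks), `p_value`,
#'   `n` (pairs), `n_zero` and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- y - x
  n <- length(d)
  if (n == 0) stop_lohscape("no pairs")
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, n = n, n_zero = n,
                method = "all-zero differences"))
  }
  r <- rank(abs(d))
  nz <- d != 0
  V <- sum(r[nz & d > 0])
  ties <- any(duplicated(abs(d[nz]))) || any(!nz)
  if (!any(!nz) && !ties && n < 20) {
    p <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    return(list(statistic = V, p_value = p, n = n, n_zero = 0,
                method = "exact"))
  }
  # Pratt: E and Var of V with zeros ranked then dropped.
  n0 <- sum(!nz)
  ev <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  tab <- table(r[nz])
  tie_corr <- sum(tab^3 - tab) / 48
  varv <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 - tie_corr
  z <- (V - ev - sign(V - ev) * 0.5) / sqrt(varv)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = V, p_value = p, n = n, n_zero = n0,
       method = "normal approximation (Pratt zeros, continuity correction)")
}

#' Paired primary-vs-recurrence comparison of scar scores
#'
#' For each patient with a scored primary and at least one scored recurrence,
#' pairs the primary with one recurrence chosen at random (seeded, recorded in
#' the output) and runs a two-sided Wilcoxon signed-rank test per metric.
#'
#' @param scores data.frame of per-sample scores (one row per sample,
#'   including a `sample_id` column and the metric columns).
#' @param metadata cohort metadata (see [read_cohort_metadata()]).
#' @param metrics character vector of score columns to test.
#' @param seed integer seed for the random recurrence choice.
#' @return list with `pairs` (data.frame: patient_id, primary_sample,
#'   recurrent_sample), `tests` (data.frame: metric, statistic, p_value, n)
#'   and the `seed` used.
#' @export
compare_paired_scores <- function(scores, metadata,
                                  metrics = c("ntai", "lst", "hrd_loh",
                                              "hrd_sum", "aneuploidy", "tmb"),
                                  seed = 1L) {
  metadata <- validate_cohort_metadata(metadata)
  m <- merge(metadata[, c("sample_id", "patient_id", "group")], scores,
             by = "sample_id")
  pairs <- with_seed(derive_seed(seed, "pairing"), {
    do.call(rbind, lapply(split(m, m$patient_id), function(d) {
      prim <- d[d$group == "primary", ]
      recs <- d[d$group == "recurrent", ]
      if (nrow(prim) != 1 || nrow(recs) < 1) return(NULL)
      pick <- recs[sample.int(nrow(recs), 1), ]
      data.frame(patient_id = d$patient_id[1],
                 primary_sample = prim$sample_id,
                 recurrent_sample = pick$sample_id, stringsAsFactors = FALSE)
    }))
  })
  if (is.null(pairs) || !nrow(pairs)) {
    stop_lohscape("no patient has both a scored primary and a scored recurrence")
  }
  rownames(pairs) <- NULL
  tests <- do.call(rbind, lapply(metrics, function(met) {
    x <- scores[[met]][match(pairs$primary_sample, scores$sample_id)]
    y <- scores[[met]][match(pairs$recurrent_sample, scores$sample_id)]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) {
      return(data.frame(metric = met, statistic = NA_real_,
                        p_value = NA_real_, n = 0L, stringsAsFactors = FALSE))
    }
    w <- wilcoxon_signed_rank(x[ok], y[ok])
    data.frame(metric = met, statistic = w$statistic, p_value = w$p_value,
               n = w$n, stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(pairs = pairs, tests = tests, seed = seed)
}
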