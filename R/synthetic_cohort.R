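# Geometry of injected scar events (bp). Chosen so every event is
# unambiguous under the default scar_config() thresholds: islands are
# separated from all other covered sequence by >= ISLAND_GAP of uncovered
# genome (>= the 3 Mb LST smoothing window, so no spurious breakpoints) and
# >= 5 Mb from each other.
ISLAND_GAP <- 3.5e6
NTAI_LEN <- 6e6      # telomeric (2,1): AI, < 10 Mb so it can never flank an LST
HRD_LOH_LEN <- 20e6  # interstitial (2,0): > 15 Mb, sub-chromosomal
LST_HALF_LEN <- 12e6 # adjacent (2,1)|(3,1), one internal qualifying breakpoint
LOH_ISLAND_LEN <- 10e6 # (1,0) around the germline locus: LOH but < 15 Mb

# -- island allocator -------------------------------------------------------

new_allocator <- function(annotation, gap = ISLAND_GAP) {
  arms <- annotation$arms
  env <- new.env(parent = emptyenv())
  env$free <- data.frame(chrom = arms$chrom, arm = arms$arm,
                         start = arms$start, end = arms$end,
                         stringsAsFactors = FALSE)
  env$annotation <- annotation
  env$gap <- gap
  env
}

# Remove [start, end] from the free space (splitting rows as needed).
reserve_zone <- function(alloc, chrom, start, end) {
  f <- alloc$free
  out <- list()
  for (i in seq_len(nrow(f))) {
    r <- f[i, ]
    if (r$chrom != chrom || r$end < start || r$start > end) {
      out[[length(out) + 1]] <- r
      next
    }
    if (r$start < start) {
      out[[length(out) + 1]] <- data.frame(chrom = r$chrom, arm = r$arm,
                                           start = r$start, end = start - 1,
                                           stringsAsFactors = FALSE)
    }
    if (r$end > end) {
      out[[length(out) + 1]] <- data.frame(chrom = r$chrom, arm = r$arm,
                                           start = end + 1, end = r$end,
                                           stringsAsFactors = FALSE)
    }
  }
  alloc$free <- do.call(rbind, out) %||%
    data.frame(chrom = character(), arm = character(), start = numeric(),
               end = numeric(), stringsAsFactors = FALSE)
  invisible(alloc)
}

# Telomeric island of `len` bp: placed flush against a chromosome end whose
# flanking free space can also absorb the uncovered gap.
alloc_telomeric <- function(alloc, len) {
  f <- alloc$free
  lens <- alloc$annotation$chrom_lengths
  ord <- order(match(f$chrom, names(lens)), f$start)
  for (i in ord) {
    r <- f[i, ]
    chrom_len <- lens[[r$chrom]]
    if (r$start == 1 && r$end - r$start + 1 >= len + alloc$gap) {
      island <- c(1, len)
    } else if (r$end == chrom_len && r$end - r$start + 1 >= len + alloc$gap) {
      island <- c(chrom_len - len + 1, chrom_len)
    } else {
      next
    }
    reserve_zone(alloc, r$chrom, island[1] - alloc$gap, island[2] + alloc$gap)
    return(data.frame(chrom = r$chrom, start = island[1], end = island[2],
                      stringsAsFactors = FALSE))
  }
  NULL
}

# Interstitial island of `len` bp with an uncovered gap on both sides.
alloc_interstitial <- function(alloc, len) {
  f <- alloc$free
  lens <- alloc$annotation$chrom_lengths
  ord <- order(match(f$chrom, names(lens)), f$start)
  for (i in ord) {
    r <- f[i, ]
    if (r$end - r$start + 1 < len + 2 * alloc$gap) next
    island <- c(r$start + alloc$gap, r$start + alloc$gap + len - 1)
    reserve_zone(alloc, r$chrom, island[1] - alloc$gap, island[2] + alloc$gap)
    return(data.frame(chrom = r$chrom, start = island[1], end = island[2],
                      stringsAsFactors = FALSE))
  }
  NULL
}

# Whole-arm event: needs a completely untouched arm; smallest arm first.
alloc_whole_arm <- function(alloc) {
  arms <- alloc$annotation$arms
  f <- alloc$free
  cand <- NULL
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    hit <- f$chrom == a$chrom & f$arm == a$arm & f$start == a$start &
      f$end == a$end
    if (any(hit)) {
      cand <- rbind(cand, a)
    }
  }
  if (is.null(cand) || !nrow(cand)) return(NULL)
  cand <- cand[order(cand$end - cand$start, cand$chrom, cand$arm), ]
  a <- cand[1, ]
  reserve_zone(alloc, a$chrom, a$start, a$end)
  data.frame(chrom = a$chrom, start = a$start, end = a$end,
             stringsAsFactors = FALSE)
}

# -- scar-event injection ---------------------------------------------------

#' Inject genomic-scar events into a segment profile
#'
#' Places the requested number of telomeric allelic-imbalance (NtAI),
#' large-scale state transition (LST), long-LOH (HRD-LOH), and whole-arm
#' aneuploidy events into the profile, on a uniformly diploid background.
#' Events are constructed to be unambiguous under the default [scar_config()]
#' thresholds: each event is an island separated from every other covered
#' region by at least 3.5 Mb of uncovered genome and at least 5 Mb from other
#' events, so scoring the returned profile recovers exactly the injected
#' counts. Existing non-diploid segments of the input profile are preserved
#' and their surroundings excluded from placement; diploid (1,1) segments are
#' treated as background and regenerated.
#'
#' @param profile a [segment_profile()] (typically all-diploid).
#' @param n_ntai,n_lst,n_hrd_loh,n_arm_events event counts (>= 0).
#' @param annotation a [genome_annotation()].
#' @return a new [segment_profile()] containing the injected events plus
#'   diploid background.
#' @export
inject_scar_events <- function(profile, n_ntai, n_lst, n_hrd_loh, annotation,
                               n_arm_events = 0) {
  stopifnot(inherits(profile, "segment_profile"))
  if (any(c(n_ntai, n_lst, n_hrd_loh, n_arm_events) < 0)) {
    stop_lohscape("event counts must be >= 0")
  }
  alloc <- new_allocator(annotation)
  seg <- profile$segments
  existing <- seg[seg$cn_major != 1 | seg$cn_minor != 1, , drop = FALSE]
  for (i in seq_len(nrow(existing))) {
    reserve_zone(alloc, existing$chrom[i], existing$start[i] - ISLAND_GAP,
                 existing$end[i] + ISLAND_GAP)
  }
  events <- place_scar_events(alloc, n_ntai, n_lst, n_hrd_loh, n_arm_events)
  build_profile_segments(alloc, rbind(existing[, c("chrom", "start", "end",
                                                   "cn_total", "cn_major",
                                                   "cn_minor")],
                                      events),
                         profile$sample_id, profile$purity, profile$ploidy)
}

place_scar_events <- function(alloc, n_ntai, n_lst, n_hrd_loh, n_arm_events) {
  mk <- function(iv, total, major, minor) {
    data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
               cn_total = total, cn_major = major, cn_minor = minor,
               stringsAsFactors = FALSE)
  }
  events <- list()
  for (k in seq_len(n_arm_events)) {
    iv <- alloc_whole_arm(alloc)
    if (is.null(iv)) stop_lohscape("no untouched chromosome arm left for ",
                                   "whole-arm event ", k)
    events[[length(events) + 1]] <- mk(iv, 4, 2, 2)
  }
  for (k in seq_len(n_ntai)) {
    iv <- alloc_telomeric(alloc, NTAI_LEN)
    if (is.null(iv)) stop_lohscape("no free telomere left for NtAI event ", k)
    events[[length(events) + 1]] <- mk(iv, 3, 2, 1)
  }
  for (k in seq_len(n_lst)) {
    iv <- alloc_interstitial(alloc, 2 * LST_HALF_LEN)
    if (is.null(iv)) stop_lohscape("insufficient interstitial capacity for ",
                                   "LST event ", k)
    mid <- iv$start + LST_HALF_LEN - 1
    events[[length(events) + 1]] <- mk(data.frame(chrom = iv$chrom,
                                                  start = iv$start, end = mid),
                                       3, 2, 1)
    events[[length(events) + 1]] <- mk(data.frame(chrom = iv$chrom,
                                                  start = mid + 1, end = iv$end),
                                       4, 3, 1)
  }
  for (k in seq_len(n_hrd_loh)) {
    iv <- alloc_interstitial(alloc, HRD_LOH_LEN)
    if (is.null(iv)) stop_lohscape("insufficient interstitial capacity for ",
                                   "HRD-LOH event ", k)
    events[[length(events) + 1]] <- mk(iv, 2, 2, 0)
  }
  do.call(rbind, events) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               cn_total = numeric(), cn_major = numeric(),
               cn_minor = numeric(), stringsAsFactors = FALSE)
}

build_profile_segments <- function(alloc, islands, sample_id, purity, ploidy) {
  background <- alloc$free
  bg <- data.frame(chrom = background$chrom, start = background$start,
                   end = background$end, cn_total = 2, cn_major = 1,
                   cn_minor = 1, stringsAsFactors = FALSE)
  seg <- rbind(islands, bg)
  seg <- seg[seg$end >= seg$start, , drop = FALSE]
  segment_profile(seg, sample_id = sample_id, purity = purity, ploidy = ploidy)
}

# -- simulation configuration ----------------------------------------------

#' Simulation configuration for a paired primary/recurrent cohort
#'
#' Defaults mirror the structure of a 27-patient breast/ovarian cohort of
#' germline BRCA1/2 carriers: 13/27 breast, most patients with a single
#' recurrence, 81% of primaries with allele-specific LOH at the germline
#' locus, modest LOH transition rates, increasing short-isoform dominance
#' from normal through primary to recurrent samples, and exponential
#' survival with hazard ratio 2.5 for short-isoform exposure.
#'
#' @param n_patients number of patients.
#' @param recurrence_dist probability vector over 1..K recurrences per
#'   patient.
#' @param p_breast probability a patient is breast (vs ovarian).
#' @param p_brca1 probability the germline gene is BRCA1 (vs BRCA2).
#' @param purity_range tumor purity range (uniform).
#' @param p_loh_primary probability the primary has LOH at the germline locus.
#' @param p_gain_loh per-recurrence probability of nonLOH -> LOH transition.
#' @param p_lose_loh per-recurrence probability of LOH -> nonLOH transition.
#' @param n_ntai,n_lst,n_hrd_loh,n_arm_events per-sample injected event
#'   counts, each a scalar or `c(min, max)` range sampled uniformly.
#' @param n_clonal clonal (shared) somatic variants per patient.
#' @param n_private private somatic variants per tumor.
#' @param p_driver_tp53 probability a patient carries a clonal TP53 LoF
#'   driver.
#' @param aaf_noise_sd s.d. of AAF noise around purity/2 for clonal
#'   heterozygous variants.
#' @param p_short_dominant named numeric: probability of short-isoform
#'   dominance per group (`normal`, `primary`, `recurrent`).
#' @param p_mutual_exclusive probability a sample expresses only one isoform
#'   (minor-isoform fraction < 0.1; otherwise both isoforms at >= 0.25).
#' @param isoform_dispersion negative-binomial size for total counts.
#' @param n_normals number of normal control samples (isoform table only).
#' @param baseline_hazard exponential event hazard per month for unexposed
#'   patients.
#' @param true_hr hazard ratio for short-isoform-exposed patients (> 0).
#' @param censor_rate target censoring fraction in [0, 1).
#' @param capture_size_mbp exome capture size used for TMB truth.
#' @param genome `"reduced"`, `"full"`, or a [genome_annotation()].
#' @param seed master seed; fixes the full cohort byte-for-byte.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 27,
                       recurrence_dist = c(0.74, 0.11, 0.07, 0.04, 0.04),
                       p_breast = 13 / 27,
                       p_brca1 = 19 / 27,
                       purity_range = c(0.4, 0.9),
                       p_loh_primary = 0.81,
                       p_gain_loh = 0.15,
                       p_lose_loh = 0.10,
                       n_ntai = c(0, 2), n_lst = c(0, 1),
                       n_hrd_loh = c(0, 1), n_arm_events = c(0, 1),
                       n_clonal = 8, n_private = 5, p_driver_tp53 = 0.8,
                       aaf_noise_sd = 0.03,
                       p_short_dominant = c(normal = 0.10, primary = 0.35,
                                            recurrent = 0.55),
                       p_mutual_exclusive = 0.97,
                       isoform_dispersion = 20,
                       n_normals = 12,
                       baseline_hazard = log(2) / 120,
                       true_hr = 2.5,
                       censor_rate = 0.2,
                       capture_size_mbp = 50,
                       genome = "reduced",
                       seed = 1L) {
  probs <- c(p_breast, p_brca1, p_loh_primary, p_gain_loh, p_lose_loh,
             p_driver_tp53, p_short_dominant, p_mutual_exclusive,
             recurrence_dist)
  if (any(probs < 0 | probs > 1)) stop_lohscape("probabilities must be in [0, 1]")
  if (abs(sum(recurrence_dist) - 1) > 1e-8) {
    stop_lohscape("recurrence_dist must sum to 1")
  }
  if (n_patients < 0 || n_clonal < 0 || n_private < 0 || n_normals < 0) {
    stop_lohscape("counts must be >= 0")
  }
  if (!(censor_rate >= 0 && censor_rate < 1)) {
    stop_lohscape("censor_rate must be in [0, 1)")
  }
  if (true_hr <= 0) stop_lohscape("true_hr must be > 0")
  if (!all(c("normal", "primary", "recurrent") %in% names(p_short_dominant))) {
    stop_lohscape("p_short_dominant needs normal/primary/recurrent entries")
  }
  annotation <- if (inherits(genome, "genome_annotation")) {
    genome
  } else if (identical(genome, "reduced")) {
    reduced_genome()
  } else if (identical(genome, "full")) {
    full_genome()
  } else {
    stop_lohscape("genome must be 'reduced', 'full' or a genome_annotation")
  }
  structure(list(
    n_patients = n_patients, recurrence_dist = recurrence_dist,
    p_breast = p_breast, p_brca1 = p_brca1, purity_range = purity_range,
    p_loh_primary = p_loh_primary, p_gain_loh = p_gain_loh,
    p_lose_loh = p_lose_loh,
    n_ntai = n_ntai, n_lst = n_lst, n_hrd_loh = n_hrd_loh,
    n_arm_events = n_arm_events,
    n_clonal = n_clonal, n_private = n_private,
    p_driver_tp53 = p_driver_tp53, aaf_noise_sd = aaf_noise_sd,
    p_short_dominant = p_short_dominant,
    p_mutual_exclusive = p_mutual_exclusive,
    isoform_dispersion = isoform_dispersion, n_normals = n_normals,
    baseline_hazard = baseline_hazard, true_hr = true_hr,
    censor_rate = censor_rate, capture_size_mbp = capture_size_mbp,
    annotation = annotation, seed = as.integer(seed)
  ), class = "sim_config")
}

sample_count <- function(spec) {
  if (length(spec) == 1 || spec[1] == spec[2]) return(as.integer(spec[1]))
  vals <- seq.int(spec[1], spec[2])
  as.integer(vals[sample.int(length(vals), 1)])
}

# Germline pathogenic locus used for each gene, per genome annotation.
germline_locus_for <- function(gene, annotation) {
  chroms <- names(annotation$chrom_lengths)
  if (length(chroms) >= 22) {
    # hg19-scale: BRCA1-like locus on 17q, BRCA2-like on 13q
    if (gene == "BRCA1") list(chrom = "chr17", pos = 41.2e6)
    else list(chrom = "chr13", pos = 32.9e6)
  } else {
    if (gene == "BRCA1") list(chrom = "chr1", pos = 60e6)
    else list(chrom = "chr2", pos = 50e6)
  }
}

GENE_PANEL <- c("TP53", "PTEN", "RB1", "NF1", "ARID1A", "PIK3CA", "AKT1",
                "KRAS", "MYC", "EGFR", "ATM", "CHEK2", "PALB2", "RAD51C",
                "MUTYH", "RAD54L", "RAD52", "KMT2C", "MAD1L1", "CASP9")

# -- cohort generation ------------------------------------------------------

#' Generate a synthetic paired primary/recurrent cohort with ground truth
#'
#' Emits the complete set of inputs the analysis pipeline consumes —
#' allele-specific segment profiles (diploid background plus injected scar
#' events and an LOH island at the germline locus when the tumor has LOH),
#' somatic variants with purity-scaled AAFs (clonal variants shared within a
#' patient, private variants per tumor), cohort metadata, two-isoform count
#' tables with mutually exclusive expression, and exponential survival times
#' with a configurable hazard ratio for short-isoform exposure — together
#' with a per-sample/per-patient truth record. Fully deterministic under the
#' config seed, with independent random streams per component.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all cohort files are
#'   written there (segments/ per-sample TSVs, variants.tsv, metadata.csv,
#'   isoform_counts.tsv, survival.csv, genome_annotation.tsv, truth.json).
#' @return list with `metadata`, `profiles` (named list), `variants`,
#'   `isoforms`, `survival`, `annotation`, `truth` (list: `samples`,
#'   `patients`), and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ann <- config$annotation
  seed <- config$seed

  cohort <- with_seed(derive_seed(seed, "cohort"), build_cohort_frame(config))
  metadata <- cohort$metadata
  truth_samples <- cohort$truth_samples
  truth_patients <- cohort$truth_patients

  profiles <- with_seed(derive_seed(seed, "segments"), {
    out <- list()
    for (i in seq_len(nrow(metadata))) {
      row <- metadata[i, ]
      tr <- truth_samples[truth_samples$sample_id == row$sample_id, ]
      alloc <- new_allocator(ann)
      # the germline-locus window is always explicitly reserved so that no
      # scar island (and no uncovered gap) can land on the locus and corrupt
      # the planted LOH status: (1,0) when the tumor has LOH, an explicit
      # diploid segment otherwise
      isl_start <- row$germline_pos - LOH_ISLAND_LEN / 2 + 1
      isl_end <- row$germline_pos + LOH_ISLAND_LEN / 2
      reserve_zone(alloc, row$germline_chrom, isl_start - ISLAND_GAP,
                   isl_end + ISLAND_GAP)
      islands <- data.frame(chrom = row$germline_chrom, start = isl_start,
                            end = isl_end,
                            cn_total = if (tr$loh) 1 else 2,
                            cn_major = 1,
                            cn_minor = if (tr$loh) 0 else 1,
                            stringsAsFactors = FALSE)
      events <- place_scar_events(alloc, tr$ntai, tr$lst, tr$hrd_loh,
                                  tr$arm_events)
      islands <- rbind(islands, events)
      out[[row$sample_id]] <- build_profile_segments(
        alloc, islands, row$sample_id, purity = tr$purity, ploidy = 2)
    }
    out
  })

  vres <- with_seed(derive_seed(seed, "variants"),
                    build_variants(config, metadata, truth_samples))
  variants <- vres$variants
  truth_samples$n_nonsyn <- vres$n_nonsyn[truth_samples$sample_id]
  truth_samples$tmb <- truth_samples$n_nonsyn / config$capture_size_mbp

  ires <- with_seed(derive_seed(seed, "isoforms"),
                    build_isoforms(config, metadata))
  isoforms <- ires$isoforms
  truth_samples$dominant_isoform <-
    ires$dominance[truth_samples$sample_id]

  exposure <- vapply(split(truth_samples, truth_samples$patient_id),
                     function(d) any(d$dominant_isoform %in% c("short", "both")),
                     logical(1))
  truth_patients$exposure <- exposure[truth_patients$patient_id]

  surv <- if (nrow(truth_patients)) {
    simulate_survival(truth_patients$patient_id, truth_patients$exposure,
                      true_hr = config$true_hr,
                      baseline_hazard = config$baseline_hazard,
                      censor_rate = config$censor_rate,
                      seed = derive_seed(seed, "survival"))
  } else {
    data.frame(patient_id = character(), os_months = numeric(),
               event = integer(), exposure = logical(),
               stringsAsFactors = FALSE)
  }
  surv$tissue <- metadata$tissue[match(surv$patient_id, metadata$patient_id)]
  surv$recurrent_status <-
    surv$patient_id %in% metadata$patient_id[metadata$group == "recurrent"]

  result <- list(metadata = metadata, profiles = profiles, variants = variants,
                 isoforms = isoforms, survival = surv, annotation = ann,
                 truth = list(samples = truth_samples,
                              patients = truth_patients),
                 config = config)
  if (!is.null(out_dir)) write_cohort(result, out_dir)
  result
}

build_cohort_frame <- function(config) {
  n <- config$n_patients
  empty_meta <- data.frame(sample_id = character(), patient_id = character(),
                           tissue = character(), timepoint = integer(),
                           group = character(), germline_gene = character(),
                           germline_chrom = character(),
                           germline_pos = numeric(), treatments = character(),
                           stringsAsFactors = FALSE)
  empty_truth <- data.frame(sample_id = character(), patient_id = character(),
                            group = character(), loh = logical(),
                            purity = numeric(), ntai = integer(),
                            lst = integer(), hrd_loh = integer(),
                            arm_events = integer(), stringsAsFactors = FALSE)
  empty_pat <- data.frame(patient_id = character(), germline_gene = character(),
                          tissue = character(), trajectory = character(),
                          stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(metadata = empty_meta, truth_samples = empty_truth,
                truth_patients = empty_pat))
  }
  meta <- list(); tsamp <- list(); tpat <- list()
  for (p in seq_len(n)) {
    pid <- sprintf("P%02d", p)
    tissue <- if (runif(1) < config$p_breast) "breast" else "ovarian"
    gene <- if (runif(1) < config$p_brca1) "BRCA1" else "BRCA2"
    locus <- germline_locus_for(gene, config$annotation)
    n_rec <- sample(seq_along(config$recurrence_dist), 1,
                    prob = config$recurrence_dist)
    status <- logical(n_rec + 1)
    status[1] <- runif(1) < config$p_loh_primary
    for (t in seq_len(n_rec)) {
      prev <- status[t]
      status[t + 1] <- if (prev) runif(1) >= config$p_lose_loh
                       else runif(1) < config$p_gain_loh
    }
    primary <- status[1]
    recs <- status[-1]
    trajectory <- if (all(recs == primary)) {
      paste0("concordant_", if (primary) "LOH" else "nonLOH")
    } else if (length(unique(recs)) > 1) {
      "mixed"
    } else if (!primary) {
      "nonLOH_to_LOH"
    } else {
      "LOH_to_nonLOH"
    }
    for (t in 0:n_rec) {
      sid <- if (t == 0) paste0(pid, "-T0") else sprintf("%s-R%d", pid, t)
      meta[[sid]] <- data.frame(
        sample_id = sid, patient_id = pid, tissue = tissue, timepoint = t,
        group = if (t == 0) "primary" else "recurrent",
        germline_gene = gene, germline_chrom = locus$chrom,
        germline_pos = locus$pos,
        treatments = if (t == 0) "none" else "chemotherapy",
        stringsAsFactors = FALSE)
      tsamp[[sid]] <- data.frame(
        sample_id = sid, patient_id = pid,
        group = if (t == 0) "primary" else "recurrent",
        loh = status[t + 1],
        purity = runif(1, config$purity_range[1], config$purity_range[2]),
        ntai = sample_count(config$n_ntai),
        lst = sample_count(config$n_lst),
        hrd_loh = sample_count(config$n_hrd_loh),
        arm_events = sample_count(config$n_arm_events),
        stringsAsFactors = FALSE)
    }
    tpat[[pid]] <- data.frame(patient_id = pid, germline_gene = gene,
                              tissue = tissue, trajectory = trajectory,
                              stringsAsFactors = FALSE)
  }
  list(metadata = do.call(rbind, meta), truth_samples = do.call(rbind, tsamp),
       truth_patients = do.call(rbind, tpat))
}

random_variant <- function(config, sample_id, gene, effect, purity) {
  ann <- config$annotation
  chrom <- sample(names(ann$chrom_lengths), 1)
  pos <- sample.int(ann$chrom_lengths[[chrom]], 1)
  aaf <- min(0.98, max(0.02, rnorm(1, purity / 2, config$aaf_noise_sd)))
  depth <- sample(60:150, 1)
  revel <- if (effect == "missense") round(runif(1), 3) else NA_real_
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
             ref = sample(c("A", "C", "G", "T"), 1),
             alt = sample(c("A", "C", "G", "T"), 1),
             gene = gene, effect = effect, aaf = round(aaf, 4),
             alt_depth = max(5, round(aaf * depth)),
             n_callers_pass = sample(1:4, 1),
             pop_freq_max = if (runif(1) < 0.1) NA_real_
                            else round(runif(1, 0, 0.005), 5),
             revel = revel, exonic = TRUE, stringsAsFactors = FALSE)
}

build_variants <- function(config, metadata, truth_samples) {
  effects <- c("missense", "synonymous", "nonsense", "frameshift")
  eff_probs <- c(0.45, 0.25, 0.15, 0.15)
  rows <- list()
  for (pid in unique(metadata$patient_id)) {
    samples <- metadata$sample_id[metadata$patient_id == pid]
    purities <- truth_samples$purity[match(samples, truth_samples$sample_id)]
    clonal <- list()
    if (runif(1) < config$p_driver_tp53) {
      clonal[[1]] <- list(gene = "TP53", effect = "nonsense")
    }
    for (k in seq_len(config$n_clonal)) {
      clonal[[length(clonal) + 1]] <-
        list(gene = sample(GENE_PANEL, 1),
             effect = sample(effects, 1, prob = eff_probs))
    }
    # clonal variants share locus/alleles across the patient's tumors
    for (cv in clonal) {
      template <- random_variant(config, samples[1], cv$gene, cv$effect,
                                 purities[1])
      for (si in seq_along(samples)) {
        v <- template
        v$sample_id <- samples[si]
        aaf <- min(0.98, max(0.02, rnorm(1, purities[si] / 2,
                                         config$aaf_noise_sd)))
        v$aaf <- round(aaf, 4)
        v$alt_depth <- max(5, round(aaf * sample(60:150, 1)))
        rows[[length(rows) + 1]] <- v
      }
    }
    for (si in seq_along(samples)) {
      for (k in seq_len(config$n_private)) {
        rows[[length(rows) + 1]] <-
          random_variant(config, samples[si], sample(GENE_PANEL, 1),
                         sample(effects, 1, prob = eff_probs), purities[si])
      }
    }
  }
  variants <- do.call(rbind, rows) %||% empty_variant_table()
  rownames(variants) <- NULL
  n_nonsyn <- vapply(
    setNames(metadata$sample_id, metadata$sample_id),
    function(s) sum(variants$sample_id == s &
                      variants$effect != "synonymous"),
    numeric(1))
  list(variants = variants, n_nonsyn = n_nonsyn)
}

build_isoforms <- function(config, metadata) {
  groups <- c(setNames(metadata$group, metadata$sample_id),
              setNames(rep("normal", config$n_normals),
                       sprintf("NORM%02d", seq_len(config$n_normals))))
  rows <- list()
  dominance <- character(0)
  for (sid in names(groups)) {
    grp <- groups[[sid]]
    short_dom <- runif(1) < config$p_short_dominant[[grp]]
    exclusive <- runif(1) < config$p_mutual_exclusive
    total <- rnbinom(1, size = config$isoform_dispersion, mu = 1000) + 50
    minor_frac <- if (exclusive) runif(1, 0, 0.1) else runif(1, 0.25, 0.5)
    if_short <- if (short_dom) 1 - minor_frac else minor_frac
    short <- round(total * if_short)
    rows[[sid]] <- data.frame(sample_id = sid, isoform_long = total - short,
                              isoform_short = short, group = grp,
                              stringsAsFactors = FALSE)
    dominance[sid] <- if (!exclusive) "both" else if (short_dom) "short" else "long"
  }
  iso <- do.call(rbind, rows) %||%
    data.frame(sample_id = character(), isoform_long = numeric(),
               isoform_short = numeric(), group = character(),
               stringsAsFactors = FALSE)
  rownames(iso) <- NULL
  list(isoforms = iso, dominance = dominance)
}

#' Simulate exponential survival with an exposure hazard ratio
#'
#' Event times are exponential with hazard `baseline_hazard * true_hr` for
#' exposed patients and `baseline_hazard` otherwise; censoring is independent
#' exponential with rate `baseline_hazard * censor_rate / (1 - censor_rate)`
#' (approximately the configured censoring fraction in the unexposed arm);
#' `censor_rate = 0` disables censoring entirely.
#'
#' @param patient_ids character vector.
#' @param exposure logical vector (same length).
#' @param true_hr hazard ratio (> 0).
#' @param baseline_hazard events per month (> 0).
#' @param censor_rate target censoring fraction in [0, 1).
#' @param seed integer seed.
#' @return data.frame: patient_id, os_months, event, exposure.
#' @export
simulate_survival <- function(patient_ids, exposure, true_hr = 2.5,
                              baseline_hazard = log(2) / 120,
                              censor_rate = 0.2, seed = 1L) {
  if (true_hr <= 0) stop_lohscape("true_hr must be > 0")
  if (!(censor_rate >= 0 && censor_rate < 1)) {
    stop_lohscape("censor_rate must be in [0, 1)")
  }
  stopifnot(length(patient_ids) == length(exposure))
  with_seed(seed, {
    n <- length(patient_ids)
    rate <- baseline_hazard * ifelse(exposure, true_hr, 1)
    t_event <- rexp(n, rate)
    if (censor_rate > 0) {
      t_cens <- rexp(n, baseline_hazard * censor_rate / (1 - censor_rate))
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(patient_id = patient_ids,
               os_months = round(pmin(t_event, t_cens), 3),
               event = as.integer(t_event <= t_cens),
               exposure = exposure, stringsAsFactors = FALSE)
  })
}

write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "segments"), recursive = TRUE,
             showWarnings = FALSE)
  for (sid in names(cohort$profiles)) {
    write_segments(cohort$profiles[[sid]],
                   file.path(out_dir, "segments", paste0(sid, ".tsv")))
  }
  write_variants(cohort$variants, file.path(out_dir, "variants.tsv"))
  write.csv(cohort$metadata, file.path(out_dir, "metadata.csv"),
            row.names = FALSE, quote = FALSE)
  write.table(cohort$isoforms, file.path(out_dir, "isoform_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(cohort$survival, file.path(out_dir, "survival.csv"),
            row.names = FALSE, quote = FALSE)
  write_genome_annotation(cohort$annotation,
                          file.path(out_dir, "genome_annotation.tsv"))
  jsonlite::write_json(
    list(samples = cohort$truth$samples, patients = cohort$truth$patients),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}
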