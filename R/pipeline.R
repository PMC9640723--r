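#' Run the full paired primary/recurrent analysis on a cohort directory
#'
#' Orchestrates all stages over a cohort laid out as written by
#' [generate_cohort()]: per-sample segment TSVs under `segments/`,
#' `variants.tsv`, `metadata.csv`, `isoform_counts.tsv`, `survival.csv` and
#' `genome_annotation.tsv`. Stage order: LOH calling/trajectories, scarring
#' scores with paired tests, gene-level copy number, somatic-variant
#' filtering/classification/ranking, and isoform usage plus survival. Stages
#' whose inputs are missing are skipped with an explicit notice in the
#' MANIFEST; every written output is listed there with its md5 hash. The run
#' is fully deterministic for a fixed `seed`.
#'
#' @param cohort_dir input directory.
#' @param out_dir output directory (created).
#' @param genes optional gene-model data.frame (see [read_gene_models()]);
#'   when NULL the gene-level CN stage is skipped.
#' @param config list of thresholds: `scar` ([scar_config()]),
#'   `capture_size_mbp`, `both_threshold`, `aaf_threshold`, `dif_threshold`.
#' @param seed integer seed (random recurrence choice in paired tests).
#' @return list of stage results, invisibly; files under `out_dir`.
#' @export
run_cohort_analysis <- function(cohort_dir, out_dir,
                                genes = NULL,
                                config = list(),
                                seed = 1L) {
  cfg <- utils::modifyList(
    list(scar = scar_config(), capture_size_mbp = 50, both_threshold = 0.2,
         aaf_threshold = 0.05, dif_threshold = 0.1),
    config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, status) {
    manifest[[length(manifest) + 1]] <<- list(stage = stage, status = status)
  }

  meta_path <- file.path(cohort_dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop_lohscape("cohort metadata not found: ", meta_path)
  }
  metadata <- read_cohort_metadata(meta_path)
  ann_path <- file.path(cohort_dir, "genome_annotation.tsv")
  annotation <- if (file.exists(ann_path)) read_genome_annotation(ann_path)
                else reduced_genome()

  seg_dir <- file.path(cohort_dir, "segments")
  profiles <- list()
  if (dir.exists(seg_dir)) {
    for (f in sort(list.files(seg_dir, pattern = "\\.tsv$", full.names = TRUE))) {
      p <- read_segments(f)
      profiles[[p$sample_id]] <- p
    }
  }

  results <- list()
  tables <- list()

  # --- LOH calling and trajectories
  if (length(profiles)) {
    loh <- cohort_loh_calls(profiles, metadata, annotation)
    results$loh <- loh
    results$loh_summary <- summarize_loh(loh)
    tables$loh_calls <- loh$calls
    tables$loh_trajectories <- loh$trajectories
    note("loh", "completed")
  } else {
    note("loh", "skipped: no segment profiles")
  }

  # --- somatic variants (needed before TMB)
  var_path <- file.path(cohort_dir, "variants.tsv")
  filtered_by_sample <- NULL
  if (file.exists(var_path)) {
    variants <- read_variants(var_path)
    filtered <- filter_somatic(variants)
    lookups <- load_synthetic_lookups()
    calls <- classify_functional(filtered, lookups$cosmic_keys, lookups$cgc)
    calls$patient_id <- metadata$patient_id[match(calls$sample_id,
                                                  metadata$sample_id)]
    calls$group <- metadata$group[match(calls$sample_id, metadata$sample_id)]
    results$variant_calls <- calls
    tables$filtered_variants <- calls
    for (grp in c("primary", "recurrent")) {
      ranked <- rank_genes_by_lof_prevalence(
        calls, grp, rnk_path = file.path(out_dir, paste0("lof_", grp, ".rnk")))
      tables[[paste0("lof_ranking_", grp)]] <- ranked
    }
    filtered_by_sample <- split(calls, calls$sample_id)
    note("variants", "completed")
  } else {
    note("variants", "skipped: no variant table")
  }

  # --- scarring scores + paired tests
  if (length(profiles)) {
    scores <- do.call(rbind, lapply(profiles, function(p) {
      v <- if (!is.null(filtered_by_sample)) filtered_by_sample[[p$sample_id]]
           else NULL
      if (is.null(v) && !is.null(filtered_by_sample)) {
        v <- empty_variant_table()
      }
      compute_scar_scores(p, annotation, cfg$scar, variants = v,
                          capture_size_mbp = cfg$capture_size_mbp)
    }))
    rownames(scores) <- NULL
    results$scores <- scores
    tables$scar_scores <- scores
    paired <- tryCatch(
      compare_paired_scores(scores, metadata, seed = seed),
      lohscape_error = function(e) NULL)
    if (!is.null(paired)) {
      results$paired_tests <- paired
      tables$paired_tests <- paired$tests
    }
    note("scarring", "completed")
  } else {
    note("scarring", "skipped: no segment profiles")
  }

  # --- gene-level copy number
  if (!is.null(genes) && length(profiles)) {
    gene_calls <- cohort_gene_cn(genes, profiles, metadata)
    results$gene_cn <- gene_calls
    tables$gene_cn <- gene_calls
    for (grp in c("primary", "recurrent")) {
      ranked <- rank_genes_by_cn_event(gene_calls, "gain_or_amp", grp)
      tables[[paste0("cn_gain_ranking_", grp)]] <- ranked
      if (nrow(ranked)) {
        write_rnk(ranked, file.path(out_dir, paste0("cn_gain_", grp, ".rnk")))
      }
    }
    note("cnv", "completed")
  } else {
    note("cnv", if (is.null(genes)) "skipped: no gene models"
                else "skipped: no segment profiles")
  }

  # --- isoform usage + survival
  iso_path <- file.path(cohort_dir, "isoform_counts.tsv")
  if (file.exists(iso_path)) {
    iso <- read_isoform_counts(iso_path)
    usage <- compute_usage(iso, both_threshold = cfg$both_threshold)
    usage$patient_id <- metadata$patient_id[match(usage$sample_id,
                                                  metadata$sample_id)]
    results$usage <- usage
    tables$isoform_usage <- usage
    note("isoform", "completed")
  } else {
    usage <- NULL
    note("isoform", "skipped: no isoform counts")
  }

  surv_path <- file.path(cohort_dir, "survival.csv")
  if (file.exists(surv_path)) {
    surv <- read_survival_table(surv_path)
    if (!"exposure" %in% names(surv) && !is.null(usage)) {
      expo <- vapply(split(usage[!is.na(usage$patient_id), ],
                           usage$patient_id[!is.na(usage$patient_id)]),
                     function(d) suppressWarnings(exposure_by_patient(d)),
                     logical(1))
      surv$exposure <- expo[surv$patient_id]
    }
    cox <- tryCatch(fit_cox(surv, covariates = "exposure"),
                    error = function(e) NULL)
    km <- tryCatch(km_medians(surv, arm = "exposure"),
                   error = function(e) NULL)
    results$cox <- cox
    results$km <- km
    if (!is.null(cox)) tables$cox <- cox
    if (!is.null(km)) tables$km_medians <- km
    note("survival", if (is.null(cox)) "completed: Cox model not estimable"
                     else "completed")
  } else {
    note("survival", "skipped: no survival table")
  }

  summary <- list(
    n_samples = nrow(metadata),
    n_patients = length(unique(metadata$patient_id)),
    loh = results$loh_summary,
    trajectories = if (!is.null(results$loh)) {
      as.list(table(results$loh$trajectories$label))
    },
    cox = if (!is.null(results$cox)) {
      list(hr = results$cox$hr[1], ci_lower = results$cox$ci_lower[1],
           ci_upper = results$cox$ci_upper[1], p = results$cox$p_value[1])
    },
    thresholds = list(
      hrd_loh_min_len = cfg$scar$hrd_loh_min_len,
      lst_min_segment = cfg$scar$lst_min_segment,
      lst_smooth_below = cfg$scar$lst_smooth_below,
      ntai_min_len = cfg$scar$ntai_min_len,
      capture_size_mbp = cfg$capture_size_mbp,
      both_threshold = cfg$both_threshold,
      aaf_threshold = cfg$aaf_threshold),
    seed = seed
  )
  write_results(tables, out_dir, summary = summary)

  files <- setdiff(list.files(out_dir, recursive = TRUE), "MANIFEST.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  jsonlite::write_json(list(stages = manifest, files = hashes),
                       file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
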