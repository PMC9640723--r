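#' Read gene models from a BED file
#'
#' BED is 0-based half-open on disk; gene models are converted to the
#' package-wide 1-based inclusive convention (this is the only boundary where
#' 0-based coordinates appear). Requires BED4 (chrom, start, end, name).
#'
#' @param path BED file path.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_lohscape("reading BED requires the rtracklayer package")
  }
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop_lohscape("cannot parse BED ", path,
                                                   ": ", conditionMessage(e)))
  df <- as.data.frame(gr)
  if (!nrow(df)) stop_lohscape("BED file has no records: ", path)
  if (is.null(df$name) || anyNA(df$name)) {
    stop_lohscape(path, ": BED4 required (every record needs a name)")
  }
  if (any(df$width < 1)) {
    stop_lohscape(path, ": record ", which(df$width < 1)[1],
                  " has start >= end")
  }
  out <- data.frame(gene = as.character(df$name),
                    chrom = normalize_chrom(as.character(df$seqnames)),
                    start = df$start, end = df$end, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write gene models to a BED4 file
#'
#' Converts the internal 1-based inclusive intervals back to BED 0-based
#' half-open coordinates.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  out <- data.frame(chrom = genes$chrom,
                    start = format(genes$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(genes$end, scientific = FALSE, trim = TRUE),
                    name = genes$gene)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read cohort metadata
#'
#' CSV with columns `sample_id, patient_id, tissue, timepoint, group,
#' germline_gene, germline_chrom, germline_pos, treatments`. Timepoint 0 is
#' the primary tumor; recurrences have timepoint >= 1. All samples of one
#' patient must share the germline gene and locus.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_cohort_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_metadata(df, source = path)
}

validate_cohort_metadata <- function(df, source = "cohort metadata") {
  need <- c("sample_id", "patient_id", "tissue", "timepoint", "group",
            "germline_gene", "germline_chrom", "germline_pos")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_lohscape(source, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop_lohscape(source, ": duplicate sample_id ",
                  df$sample_id[duplicated(df$sample_id)][1])
  }
  if (!all(df$tissue %in% c("breast", "ovarian"))) {
    stop_lohscape(source, ": tissue must be breast or ovarian")
  }
  if (!all(df$group %in% c("primary", "recurrent"))) {
    stop_lohscape(source, ": group must be primary or recurrent")
  }
  if (!all((df$timepoint == 0) == (df$group == "primary"))) {
    stop_lohscape(source, ": timepoint 0 must coincide with group == primary")
  }
  if (!all(df$germline_gene %in% c("BRCA1", "BRCA2"))) {
    stop_lohscape(source, ": germline_gene must be BRCA1 or BRCA2")
  }
  df$germline_chrom <- normalize_chrom(as.character(df$germline_chrom))
  per_pat <- split(df[, c("germline_gene", "germline_chrom", "germline_pos")],
                   df$patient_id)
  for (p in names(per_pat)) {
    if (nrow(unique(per_pat[[p]])) != 1) {
      stop_lohscape(source, ": samples of patient ", p,
                    " disagree on the germline locus")
    }
  }
  rownames(df) <- NULL
  df
}

#' Read a two-isoform count table
#'
#' TSV with columns `sample_id, isoform_long, isoform_short` (non-negative
#' expression counts for the canonical long and the alternative short
#' transcript of one gene).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_isoform_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "isoform_long", "isoform_short")
  if (!all(need %in% names(df))) {
    stop_lohscape(path, ": isoform table needs columns ",
                  paste(need, collapse = ", "))
  }
  if (any(df$isoform_long < 0 | df$isoform_short < 0)) {
    stop_lohscape(path, ": negative isoform counts")
  }
  df
}

#' Read a per-patient survival table
#'
#' CSV with columns `patient_id, os_months, event` plus optional covariate
#' columns (e.g. `tissue`, `recurrent_status`, `exposure`). `os_months` must
#' be positive; `event` is 1 for death, 0 for censoring.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_survival_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "os_months", "event")
  if (!all(need %in% names(df))) {
    stop_lohscape(path, ": survival table needs columns ",
                  paste(need, collapse = ", "))
  }
  if (any(df$os_months <= 0)) stop_lohscape(path, ": os_months must be > 0")
  if (!all(df$event %in% c(0, 1))) stop_lohscape(path, ": event must be 0/1")
  df
}

#' Write a GSEA Preranked .rnk file
#'
#' Two tab-separated columns (gene, score), no header, in the order given —
#' callers are expected to pass a deterministically ranked list (see
#' [rank_genes_by_lof_prevalence()]).
#'
#' @param ranked data.frame with columns `gene` and `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  write.table(ranked[, c("gene", "score")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a set of result tables plus a JSON summary
#'
#' Each element of `tables` is written as `<name>.tsv` under `dir`;
#' `summary` (a list) is written as `summary.json`.
#'
#' @param tables named list of data.frames (may be empty).
#' @param dir output directory (created if needed).
#' @param summary optional list serialized to JSON.
#' @return character vector of written paths, invisibly.
#' @export
write_results <- function(tables, dir, summary = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(format_numeric_df(tables[[nm]]), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(summary)) {
    p <- file.path(dir, "summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
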