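VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                     "effect", "aaf", "alt_depth", "n_callers_pass",
                     "pop_freq_max", "revel", "exonic")

VARIANT_EFFECTS <- c("frameshift", "nonsense", "missense", "synonymous",
                     "splice", "other")

# Empty variant table with the documented schema.
empty_variant_table <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = numeric(),
             ref = character(), alt = character(), gene = character(),
             effect = character(), aaf = numeric(), alt_depth = numeric(),
             n_callers_pass = numeric(), pop_freq_max = numeric(),
             revel = numeric(), exonic = logical(), stringsAsFactors = FALSE)
}

validate_variants <- function(df, source = "variant table") {
  missing <- setdiff(setdiff(VARIANT_COLUMNS, c("pop_freq_max", "revel")),
                     names(df))
  if (length(missing)) {
    stop_lohscape(source, ": missing mandatory column(s) ",
                  paste(missing, collapse = ", "))
  }
  if (!"pop_freq_max" %in% names(df)) df$pop_freq_max <- NA_real_
  if (!"revel" %in% names(df)) df$revel <- NA_real_
  df <- df[, VARIANT_COLUMNS, drop = FALSE]
  df$chrom <- normalize_chrom(as.character(df$chrom))
  num <- c("pos", "aaf", "alt_depth", "n_callers_pass", "pop_freq_max", "revel")
  for (cl in num) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  df$exonic <- as.logical(df$exonic)
  mandatory <- c("pos", "aaf", "alt_depth", "n_callers_pass")
  for (cl in mandatory) {
    if (anyNA(df[[cl]])) {
      stop_lohscape(source, ": missing/malformed mandatory field '", cl,
                    "' at record ", which(is.na(df[[cl]]))[1])
    }
  }
  if (anyNA(df$exonic)) {
    stop_lohscape(source, ": missing mandatory field 'exonic' at record ",
                  which(is.na(df$exonic))[1])
  }
  bad <- which(df$aaf < 0 | df$aaf > 1)
  if (length(bad)) {
    stop_lohscape(source, ": aaf out of [0,1] at record ", bad[1])
  }
  unknown <- setdiff(unique(df$effect), VARIANT_EFFECTS)
  if (length(unknown)) {
    stop_lohscape(source, ": unknown effect class(es) ",
                  paste(unknown, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read a somatic variant table (flat TSV or minimal VCF)
#'
#' The package defines its own flat tab-separated variant dialect with header
#' columns `sample_id, chrom, pos, ref, alt, gene, effect, aaf, alt_depth,
#' n_callers_pass, pop_freq_max, revel, exonic`. `effect` is one of
#' `frameshift, nonsense, missense, synonymous, splice, other`; `exonic` is
#' TRUE/FALSE. Unknown population frequency or REVEL scores are written as
#' `NA` (or `.`) and read back as `NA` — an explicit "unknown" marker, never a
#' silent default. Alternatively a minimal VCF v4.2 subset is supported
#' (requires the vcfR package): one sample per file, annotations in INFO keys
#' `GENE, EFFECT, AAF, ALT_DP, NCALL, POPFREQ, REVEL, EXONIC`.
#'
#' @param path file path; format detected from content (`##fileformat=VCF`)
#'   or the `.vcf` extension.
#' @return data.frame of somatic variants (possibly 0-row, with a warning for
#'   an empty file).
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && (grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path))) {
    return(read_variants_vcf(path))
  }
  if (!length(first) || !nzchar(first)) {
    warning("empty variant file: ", path)
    return(empty_variant_table())
  }
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."),
                   colClasses = "character")
  if (!nrow(df)) {
    warning("variant file has no records: ", path)
    return(empty_variant_table())
  }
  validate_variants(df, source = path)
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_lohscape("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixmat <- vcfR::getFIX(v)
  if (is.null(dim(fixmat))) {
    fixmat <- matrix(fixmat, nrow = 1, dimnames = list(NULL, names(fixmat)))
  }
  fix <- as.data.frame(fixmat, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    warning("VCF has no records: ", path)
    return(empty_variant_table())
  }
  info_num <- function(key) suppressWarnings(as.numeric(vcfR::extract.info(v, key)))
  info_chr <- function(key) as.character(vcfR::extract.info(v, key))
  sample_id <- sub("^##lohscape_sample=", "",
                   grep("^##lohscape_sample=", v@meta, value = TRUE)[1])
  if (is.na(sample_id)) sample_id <- sub("\\.vcf$", "", basename(path))
  df <- data.frame(
    sample_id = sample_id,
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    gene = info_chr("GENE"), effect = info_chr("EFFECT"),
    aaf = info_num("AAF"), alt_depth = info_num("ALT_DP"),
    n_callers_pass = info_num("NCALL"), pop_freq_max = info_num("POPFREQ"),
    revel = info_num("REVEL"),
    exonic = info_chr("EXONIC") %in% c("1", "TRUE", "yes"),
    stringsAsFactors = FALSE
  )
  validate_variants(df, source = path)
}

#' Write a somatic variant table
#'
#' Writes the flat TSV dialect read by [read_variants()]; `NA` marks unknown
#' optional annotations.
#'
#' @param variants variant data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  variants <- validate_variants(variants, source = "write_variants input")
  write.table(format_numeric_df(variants), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Canonical variant key
#'
#' `chrom:pos:ref:alt` string used for COSMIC-style membership lookups and
#' shared-variant matrices.
#'
#' @param variants variant data.frame.
#' @return character vector of keys.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, format(variants$pos, scientific = FALSE, trim = TRUE),
        variants$ref, variants$alt, sep = ":")
}
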