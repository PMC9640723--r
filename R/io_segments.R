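#' Construct and validate an allele-specific segment profile
#'
#' A `segment_profile` is one tumor sample's allele-specific copy-number
#' segmentation: per segment the total, major (A) and minor (B) allele copy
#' numbers, plus sample-level purity and ploidy estimates. All coordinates are
#' 1-based inclusive. Segments must be non-overlapping within a chromosome and
#' satisfy `cn_major >= cn_minor >= 0` and `cn_major + cn_minor == cn_total`.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `cn_total`, `cn_major`, `cn_minor`.
#' @param sample_id sample identifier.
#' @param purity tumor cell fraction in (0, 1].
#' @param ploidy average tumor ploidy (> 0).
#' @return An object of class `segment_profile`.
#' @export
segment_profile <- function(segments, sample_id, purity = 1, ploidy = 2) {
  need <- c("chrom", "start", "end", "cn_total", "cn_major", "cn_minor")
  if (!all(need %in% names(segments))) {
    stop_lohscape("segments need columns ", paste(need, collapse = ", "))
  }
  segments <- segments[, need, drop = FALSE]
  segments$chrom <- normalize_chrom(as.character(segments$chrom))
  for (cl in need[-1]) segments[[cl]] <- as.numeric(segments[[cl]])
  if (!(purity > 0 && purity <= 1)) stop_lohscape("purity must be in (0, 1]")
  if (!(ploidy > 0)) stop_lohscape("ploidy must be > 0")

  bad <- which(segments$start > segments$end)
  if (length(bad)) {
    stop_lohscape("segment ", bad[1], " (", segments$chrom[bad[1]], ":",
                  segments$start[bad[1]], "-", segments$end[bad[1]],
                  ") has start > end")
  }
  bad <- which(segments$cn_major < segments$cn_minor |
                 segments$cn_minor < 0 |
                 segments$cn_major + segments$cn_minor != segments$cn_total)
  if (length(bad)) {
    i <- bad[1]
    stop_lohscape(
      "invalid allele-specific copy numbers for segment ", segments$chrom[i],
      ":", segments$start[i], "-", segments$end[i],
      " (total=", segments$cn_total[i], ", major=", segments$cn_major[i],
      ", minor=", segments$cn_minor[i],
      "); need major >= minor >= 0 and major + minor == total")
  }

  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      j <- which(s$start[-1] <= s$end[-nrow(s)])[1]
      stop_lohscape("overlapping segments on ", ch, ": ", s$start[j], "-",
                    s$end[j], " and ", s$start[j + 1], "-", s$end[j + 1])
    }
  }

  structure(list(sample_id = sample_id, segments = segments,
                 purity = purity, ploidy = ploidy),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("<segment_profile> ", x$sample_id, ": ", nrow(x$segments),
      " segments on ", length(unique(x$segments$chrom)),
      " chromosomes; purity=", x$purity, ", ploidy=", x$ploidy, "\n", sep = "")
  invisible(x)
}

segment_lengths <- function(segments) segments$end - segments$start + 1

#' Read an allele-specific copy-number segment table
#'
#' Reads a Sequenza-style tab-separated segment file with header columns
#' `chromosome`, `start`, `end`, `cn_total`, `cn_major`, `cn_minor`
#' (coordinates 1-based inclusive). Lines starting with `#` may carry
#' sample metadata as `# key=value` (recognized keys: `sample_id`, `purity`,
#' `ploidy`); explicit arguments override them.
#'
#' @param path file path.
#' @param sample_id,purity,ploidy optional overrides for the file metadata.
#'   Defaults when absent everywhere: basename of `path`, purity 1, ploidy 2.
#' @return A [segment_profile()].
#' @export
read_segments <- function(path, sample_id = NULL, purity = NULL, ploidy = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || !nzchar(body[1])) stop_lohscape("empty segment file: ", path)
  df <- tryCatch(
    read.delim(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE),
    error = function(e) stop_lohscape("cannot parse ", path, ": ", conditionMessage(e)))
  need <- c("chromosome", "start", "end", "cn_total", "cn_major", "cn_minor")
  if (!all(need %in% names(df))) {
    stop_lohscape(path, ": segment file must have header columns ",
                  paste(need, collapse = ", "))
  }
  for (cl in need[-1]) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v)) {
      stop_lohscape(path, ": malformed value in column '", cl, "' at data line ",
                    which(is.na(v))[1])
    }
    df[[cl]] <- v
  }
  names(df)[names(df) == "chromosome"] <- "chrom"
  segment_profile(
    df,
    sample_id = sample_id %||% meta$sample_id %||%
      sub("\\.[^.]*$", "", basename(path)),
    purity = as.numeric(purity %||% meta$purity %||% 1),
    ploidy = as.numeric(ploidy %||% meta$ploidy %||% 2)
  )
}

#' Write an allele-specific copy-number segment table
#'
#' Inverse of [read_segments()]; sample metadata are stored in `# key=value`
#' header lines so a read/write cycle is lossless.
#'
#' @param profile a [segment_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profile, path) {
  stopifnot(inherits(profile, "segment_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sample_id=", profile$sample_id),
               paste0("# purity=", format(profile$purity, scientific = FALSE)),
               paste0("# ploidy=", format(profile$ploidy, scientific = FALSE))), con)
  out <- profile$segments
  names(out)[names(out) == "chrom"] <- "chromosome"
  write.table(format_numeric_df(out), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
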