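#' Genome annotation: chromosome lengths, arms, and centromeres
#'
#' A `genome_annotation` holds per-chromosome lengths, p/q arm intervals
#' (1-based inclusive) and the centromere interval separating them. Arm
#' definitions drive the telomere/centromere logic of the scarring scores
#' (telomeric allelic imbalance must reach a chromosome end without crossing
#' the centromere) and the arm-level aneuploidy score.
#'
#' @param chrom character vector of chromosome names ("chr"-prefixed).
#' @param length chromosome lengths in bp.
#' @param p_end last base of the p arm (p arm is `[1, p_end]`).
#' @param q_start first base of the q arm (q arm is `[q_start, length]`).
#'   The centromere is `[p_end + 1, q_start - 1]` and must be non-empty.
#' @return An object of class `genome_annotation` with elements
#'   `chrom_lengths` (named numeric), `arms` (data.frame: chrom, arm, start,
#'   end) and `centromere` (data.frame: chrom, start, end).
#' @export
genome_annotation <- function(chrom, length, p_end, q_start) {
  stopifnot(is.character(chrom), !anyDuplicated(chrom))
  chrom <- normalize_chrom(chrom)
  if (any(p_end < 1 | q_start <= p_end + 1 | q_start > length)) {
    stop_lohscape("invalid arm boundaries: need 1 <= p_end < q_start - 1 <= length")
  }
  arms <- rbind(
    data.frame(chrom = chrom, arm = "p", start = 1, end = p_end,
               stringsAsFactors = FALSE),
    data.frame(chrom = chrom, arm = "q", start = q_start, end = length,
               stringsAsFactors = FALSE)
  )
  arms <- arms[order(match(arms$chrom, chrom), arms$start), , drop = FALSE]
  rownames(arms) <- NULL
  ann <- structure(
    list(
      chrom_lengths = setNames(as.numeric(length), chrom),
      arms = arms,
      centromere = data.frame(chrom = chrom, start = p_end + 1,
                              end = q_start - 1, stringsAsFactors = FALSE)
    ),
    class = "genome_annotation"
  )
  validate_genome_annotation(ann)
}

validate_genome_annotation <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  for (i in seq_len(nrow(ann$arms))) {
    a <- ann$arms[i, ]
    len <- ann$chrom_lengths[[a$chrom]]
    if (a$start < 1 || a$end > len) {
      stop_lohscape("arm ", a$chrom, a$arm, " exceeds chromosome length")
    }
  }
  for (ch in names(ann$chrom_lengths)) {
    p <- ann$arms[ann$arms$chrom == ch & ann$arms$arm == "p", ]
    q <- ann$arms[ann$arms$chrom == ch & ann$arms$arm == "q", ]
    cen <- ann$centromere[ann$centromere$chrom == ch, ]
    if (p$end >= q$start) stop_lohscape("arms of ", ch, " overlap")
    if (cen$start != p$end + 1 || cen$end != q$start - 1) {
      stop_lohscape("centromere of ", ch, " does not flank the arms")
    }
  }
  ann
}

#' @describeIn genome_annotation Reduced 3-chromosome, 200 Mb genome used as
#'   the fast default for simulation and tests.
#' @export
reduced_genome <- function() {
  genome_annotation(
    chrom   = c("chr1", "chr2", "chr3"),
    length  = c(90e6, 70e6, 40e6),
    p_end   = c(40e6, 30e6, 16e6),
    q_start = c(45e6 + 1, 34e6 + 1, 20e6 + 1)
  )
}

#' @describeIn genome_annotation hg19-scale 22-autosome annotation with
#'   approximate (Mb-rounded) centromere positions, for capacity-hungry
#'   simulations. Coordinates are approximate and intended for synthetic data.
#' @export
full_genome <- function() {
  len <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
           115, 107, 103, 90, 81, 78, 59, 63, 48, 51) * 1e6
  cen_lo <- c(121, 92, 90, 49, 46, 58, 58, 43, 47, 39, 51, 34,
              16, 16, 17, 35, 22, 15, 24, 26, 11, 13) * 1e6
  cen_hi <- c(128, 95, 93, 52, 50, 62, 62, 47, 51, 42, 55, 38,
              20, 20, 21, 39, 26, 19, 28, 30, 14, 17) * 1e6
  genome_annotation(
    chrom = paste0("chr", 1:22),
    length = len,
    p_end = cen_lo - 1,
    q_start = cen_hi + 1
  )
}

#' Read a chromosome-arm annotation table
#'
#' Expects a tab-separated file with header columns `chrom`, `arm` (p or q),
#' `start`, `end` (1-based inclusive), two rows per chromosome. The p arm must
#' start at base 1 and the q arm end defines the chromosome length; the gap
#' between the arms is the centromere.
#'
#' @param path file path.
#' @return A [genome_annotation()].
#' @export
read_genome_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "arm", "start", "end")
  if (!all(need %in% names(df))) {
    stop_lohscape("annotation file must have columns ", paste(need, collapse = ", "))
  }
  df$chrom <- normalize_chrom(df$chrom)
  p <- df[df$arm == "p", ]
  q <- df[df$arm == "q", ]
  if (!setequal(p$chrom, q$chrom) || any(p$start != 1)) {
    stop_lohscape("annotation must define p (starting at 1) and q arms for every chromosome")
  }
  q <- q[match(p$chrom, q$chrom), ]
  genome_annotation(chrom = p$chrom, length = q$end,
                    p_end = p$end, q_start = q$start)
}

#' Write a chromosome-arm annotation table
#'
#' Inverse of [read_genome_annotation()].
#'
#' @param ann a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_annotation <- function(ann, path) {
  write.table(format_numeric_df(ann$arms), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# "chr"-prefix normalization; strict = reject mixed naming.
normalize_chrom <- function(x, strict = FALSE) {
  has <- grepl("^chr", x)
  if (strict && any(has) && !all(has)) {
    stop_lohscape("mixed chromosome naming (some 'chr'-prefixed, some not)")
  }
  ifelse(has, x, paste0("chr", x))
}

# write.table prints large integers in scientific notation by default;
# format them as plain integers for byte-stable files.
format_numeric_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- format(df[[nm]], scientific = FALSE, trim = TRUE)
  }
  df
}
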