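# Shared fixtures: tiny profiles, annotations and variant rows built in code.

mk_segments <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), cn_total = as.numeric(r[[4]]),
               cn_major = as.numeric(r[[5]]), cn_minor = as.numeric(r[[6]]),
               stringsAsFactors = FALSE)
  }))
}

mk_profile <- function(..., sample_id = "S1", purity = 1, ploidy = 2) {
  segment_profile(mk_segments(...), sample_id, purity, ploidy)
}

# one 100 Mb chromosome: p = 1-45 Mb, centromere 45-50 Mb, q = 50-100 Mb
toy_genome <- function() {
  genome_annotation("chr1", length = 100e6, p_end = 45e6, q_start = 50e6 + 1)
}

diploid_profile <- function(ann, sample_id = "S1", purity = 1) {
  arms <- ann$arms
  segment_profile(
    data.frame(chrom = arms$chrom, start = arms$start, end = arms$end,
               cn_total = 2, cn_major = 1, cn_minor = 1,
               stringsAsFactors = FALSE),
    sample_id, purity, 2)
}

mk_variant <- function(sample_id = "S1", chrom = "chr1", pos = 1000,
                       ref = "A", alt = "T", gene = "TP53",
                       effect = "missense", aaf = 0.3, alt_depth = 20,
                       n_callers_pass = 2, pop_freq_max = 0.001,
                       revel = NA_real_, exonic = TRUE) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, effect = effect, aaf = aaf,
             alt_depth = alt_depth, n_callers_pass = n_callers_pass,
             pop_freq_max = pop_freq_max, revel = revel, exonic = exonic,
             stringsAsFactors = FALSE)
}

mk_metadata <- function(n_pat = 2, recs = 1, tissue = "breast",
                        gene = "BRCA1", chrom = "chr1", pos = 60e6) {
  rows <- list()
  for (p in seq_len(n_pat)) {
    pid <- sprintf("P%02d", p)
    for (t in 0:recs) {
      sid <- if (t == 0) paste0(pid, "-T0") else sprintf("%s-R%d", pid, t)
      rows[[sid]] <- data.frame(
        sample_id = sid, patient_id = pid, tissue = tissue, timepoint = t,
        group = if (t == 0) "primary" else "recurrent",
        germline_gene = gene, germline_chrom = chrom, germline_pos = pos,
        treatments = "none", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Random small profile on a 2-chromosome toy genome, exercising gaps, ties
# and all allele-specific states; used for oracle-equivalence checks.
random_profile_genome <- function() {
  genome_annotation(c("chr1", "chr2"), length = c(120e6, 80e6),
                    p_end = c(50e6, 30e6), q_start = c(56e6 + 1, 35e6 + 1))
}

random_profile <- function(ann = random_profile_genome(), max_segments = 12) {
  states <- list(c(1, 1), c(2, 0), c(2, 1), c(3, 1), c(0, 0), c(2, 2),
                 c(1, 0), c(3, 0))
  segs <- list()
  for (ch in names(ann$chrom_lengths)) {
    n <- sample.int(max_segments, 1)
    len <- ann$chrom_lengths[[ch]]
    bp <- sort(sample.int(len, 2 * n))
    for (i in seq_len(n)) {
      st <- states[[sample.int(length(states), 1)]]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start = bp[2 * i - 1], end = bp[2 * i],
        cn_total = st[1] + st[2], cn_major = st[1], cn_minor = st[2],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, segs)
  # drop zero-length/overlapping artifacts from duplicated breakpoints
  keep <- df$start <= df$end
  df <- df[keep, , drop = FALSE]
  ok <- unlist(lapply(split(seq_len(nrow(df)), df$chrom), function(idx) {
    idx <- idx[order(df$start[idx])]
    sel <- logical(length(idx))
    last_end <- -1
    for (k in seq_along(idx)) {
      if (df$start[idx[k]] > last_end) {
        sel[k] <- TRUE
        last_end <- df$end[idx[k]]
      }
    }
    idx[sel]
  }))
  segment_profile(df[sort(ok), , drop = FALSE], "RND", 1, 2)
}
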