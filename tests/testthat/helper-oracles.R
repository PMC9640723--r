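# Independent brute-force scorers. Deliberately naive O(n^2) enumeration,
# written against the documented scoring rules, not against the package
# internals; used to validate the optimized implementations.

oracle_hrd_loh <- function(profile, ann, cfg = scar_config()) {
  seg <- profile$segments
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    len <- s$end - s$start + 1
    if (s$cn_minor == 0 && len > cfg$hrd_loh_min_len &&
        len < ann$chrom_lengths[[s$chrom]]) {
      n <- n + 1L
    }
  }
  n
}

oracle_ntai <- function(profile, ann, cfg = scar_config()) {
  seg <- profile$segments
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    len <- s$end - s$start + 1
    chrom_len <- ann$chrom_lengths[[s$chrom]]
    cen <- ann$centromere[ann$centromere$chrom == s$chrom, ]
    at_telomere <- (s$start <= 1 + cfg$telomere_tolerance) ||
      (s$end >= chrom_len - cfg$telomere_tolerance)
    spans_centromere <- s$start < cen$start && s$end > cen$end
    if (s$cn_major != s$cn_minor && at_telomere && !spans_centromere &&
        len < chrom_len && len >= cfg$ntai_min_len) {
      n <- n + 1L
    }
  }
  n
}

# LST oracle: remove-smallest-first smoothing with bridging merges, then a
# pairwise scan over consecutive segments.
oracle_lst <- function(profile, cfg = scar_config()) {
  count <- 0L
  for (ch in unique(profile$segments$chrom)) {
    s <- profile$segments[profile$segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    repeat {
      changed <- FALSE
      # merge any same-state neighbors with gap below the window
      i <- 1
      while (i < nrow(s)) {
        gap <- s$start[i + 1] - s$end[i] - 1
        if (gap < cfg$lst_smooth_below &&
            s$cn_major[i] == s$cn_major[i + 1] &&
            s$cn_minor[i] == s$cn_minor[i + 1]) {
          s$end[i] <- s$end[i + 1]
          s <- s[-(i + 1), , drop = FALSE]
          changed <- TRUE
        } else {
          i <- i + 1
        }
      }
      # remove the smallest sub-window segment, one at a time
      lens <- s$end - s$start + 1
      small <- which(lens < cfg$lst_smooth_below)
      if (length(small)) {
        drop <- small[which.min(lens[small])]
        s <- s[-drop, , drop = FALSE]
        changed <- TRUE
      }
      if (!changed) break
    }
    if (nrow(s) < 2) next
    for (i in seq_len(nrow(s) - 1)) {
      gap <- s$start[i + 1] - s$end[i] - 1
      len_l <- s$end[i] - s$start[i] + 1
      len_r <- s$end[i + 1] - s$start[i + 1] + 1
      differs <- s$cn_major[i] != s$cn_major[i + 1] ||
        s$cn_minor[i] != s$cn_minor[i + 1]
      if (differs && gap < cfg$lst_smooth_below &&
          len_l >= cfg$lst_min_segment && len_r >= cfg$lst_min_segment) {
        count <- count + 1L
      }
    }
  }
  count
}

# Per-basepair support count for minimal-common-region, on toy coordinates.
oracle_mcr <- function(interval_sets, min_support, genome_size = 1e4) {
  support <- integer(genome_size)
  for (s in seq_along(interval_sets)) {
    covered <- logical(genome_size)
    df <- interval_sets[[s]]
    for (i in seq_len(nrow(df))) {
      covered[df$start[i]:df$end[i]] <- TRUE
    }
    support <- support + covered
  }
  top <- max(support)
  if (top < min_support) return(NULL)
  first <- which(support == top)[1]
  last <- first
  while (last < genome_size && support[last + 1] == top) last <- last + 1
  list(start = first, end = last, support = top)
}
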