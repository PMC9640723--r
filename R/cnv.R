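CN_CATEGORIES <- c("Deletion", "Loss", "Neutral", "Gain", "Amplification")

#' Bin total copy number into categories
#'
#' CN 0 = Deletion; CN 1 = Loss; CN 2-3 = Neutral; CN 4-5 = Gain;
#' CN >= 6 = Amplification.
#'
#' @param cn_total non-negative integer vector of total copy numbers.
#' @return character vector of categories.
#' @export
bin_copy_number <- function(cn_total) {
  if (any(cn_total < 0)) stop_lohscape("copy number must be >= 0")
  cut_idx <- findInterval(cn_total, c(0, 1, 2, 4, 6))
  CN_CATEGORIES[cut_idx]
}

#' Gene-level copy-number annotation
#'
#' The gene's copy number is the minimal total copy number over all segments
#' intersecting the locus (covered parts only). Additionally, a gene
#' `qualifies_deleted` when more than 50% of the locus is covered by
#' Deletion-binned (CN 0) segments, and `qualifies_amplified` only when 100%
#' of the locus is covered by Amplification-binned (CN >= 6) segments.
#' Portions of the gene not covered by any segment count toward neither
#' fraction; the total covered fraction is reported so poorly covered genes
#' can be filtered.
#'
#' @param gene 1-row data.frame or list with `gene`, `chrom`, `start`, `end`.
#' @param profile a [segment_profile()].
#' @return 1-row data.frame: gene, min_cn, category, covered_fraction,
#'   deletion_fraction, amplification_fraction, qualifies_deleted,
#'   qualifies_amplified. A gene on a chromosome absent from the profile (or
#'   with no intersecting segment) yields a no-call (NA min_cn/category) with
#'   a warning.
#' @export
annotate_gene_cn <- function(gene, profile) {
  seg <- profile$segments
  glen <- gene$end - gene$start + 1
  hit <- seg[seg$chrom == gene$chrom & seg$start <= gene$end &
               seg$end >= gene$start, , drop = FALSE]
  if (!nrow(hit)) {
    warning("gene ", gene$gene, " has no covering segment in ",
            profile$sample_id, "; no-call")
    return(data.frame(gene = gene$gene, min_cn = NA_real_,
                      category = NA_character_, covered_fraction = 0,
                      deletion_fraction = 0, amplification_fraction = 0,
                      qualifies_deleted = FALSE, qualifies_amplified = FALSE,
                      stringsAsFactors = FALSE))
  }
  ov <- pmin(hit$end, gene$end) - pmax(hit$start, gene$start) + 1
  cat <- bin_copy_number(hit$cn_total)
  min_cn <- min(hit$cn_total)
  del_frac <- sum(ov[cat == "Deletion"]) / glen
  amp_frac <- sum(ov[cat == "Amplification"]) / glen
  data.frame(gene = gene$gene, min_cn = min_cn,
             category = bin_copy_number(min_cn),
             covered_fraction = sum(ov) / glen,
             deletion_fraction = del_frac,
             amplification_fraction = amp_frac,
             qualifies_deleted = del_frac > 0.5,
             qualifies_amplified = amp_frac == 1,
             stringsAsFactors = FALSE)
}

#' Gene-level annotation across a cohort
#'
#' @param genes gene models (see [read_gene_models()]).
#' @param profiles named list of [segment_profile()]s.
#' @param metadata cohort metadata.
#' @return data.frame of gene calls with sample_id, patient_id, group columns.
#' @export
cohort_gene_cn <- function(genes, profiles, metadata) {
  metadata <- validate_cohort_metadata(metadata)
  out <- list()
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[i]
    prof <- profiles[[sid]]
    if (is.null(prof)) next
    calls <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
      suppressWarnings(annotate_gene_cn(genes[g, ], prof))
    }))
    calls$sample_id <- sid
    calls$patient_id <- metadata$patient_id[i]
    calls$group <- metadata$group[i]
    out[[sid]] <- calls
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

interval_intersection <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
}

#' Reciprocal overlap between two intervals
#'
#' TRUE when the intersection covers at least fraction `f` of *each*
#' interval's own length (BEDtools `-f x -r` semantics).
#'
#' @param a,b lists/rows with `chrom`, `start`, `end`.
#' @param f required fraction in (0, 1], default 0.5.
#' @return single logical.
#' @export
reciprocal_overlap <- function(a, b, f = 0.5) {
  stopifnot(f > 0, f <= 1)
  if (a$chrom != b$chrom) return(FALSE)
  inter <- interval_intersection(a$start, a$end, b$start, b$end)
  inter >= f * (a$end - a$start + 1) && inter >= f * (b$end - b$start + 1)
}

# Total length of the union of a set of intervals (data.frame chrom/start/end).
union_length <- function(df) {
  if (!nrow(df)) return(0)
  tot <- 0
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    cur_s <- s$start[1]; cur_e <- s$end[1]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] <= cur_e + 1) {
        cur_e <- max(cur_e, s$end[i])
      } else {
        tot <- tot + cur_e - cur_s + 1
        cur_s <- s$start[i]; cur_e <- s$end[i]
      }
    }
    tot <- tot + cur_e - cur_s + 1
  }
  tot
}

#' Shared/private classification and Jaccard similarity of two segment sets
#'
#' Segments from the two sets are paired greedily by intersection length
#' (ties broken by coordinates, deterministic); a pair is "shared" when it has
#' at least `f` reciprocal overlap, and each segment can be shared with at
#' most one partner. Unpaired segments are private to their set. The Jaccard
#' index is the total basepair length of shared-pair intersections divided by
#' the basepair length of the union of all segments in both sets.
#'
#' @param set_a,set_b data.frames with `chrom`, `start`, `end`.
#' @param f reciprocal-overlap fraction (default 0.5).
#' @return list of class `segment_set_comparison`: `shared` (data.frame of
#'   paired intervals with their intersection), `private_a`, `private_b`,
#'   `jaccard`.
#' @export
compare_segment_sets <- function(set_a, set_b, f = 0.5) {
  stopifnot(f > 0, f <= 1)
  na <- nrow(set_a); nb <- nrow(set_b)
  cand <- NULL
  if (na && nb) {
    cand <- do.call(rbind, lapply(seq_len(na), function(i) {
      a <- set_a[i, ]
      inter <- interval_intersection(a$start, a$end, set_b$start, set_b$end)
      inter[set_b$chrom != a$chrom] <- 0
      ok <- which(inter >= f * (a$end - a$start + 1) &
                    inter >= f * (set_b$end - set_b$start + 1) & inter > 0)
      if (!length(ok)) return(NULL)
      data.frame(i = i, j = ok, inter = inter[ok])
    }))
  }
  matched <- NULL
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(-cand$inter, cand$i, cand$j), , drop = FALSE]
    used_a <- logical(na); used_b <- logical(nb)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!used_a[cand$i[k]] && !used_b[cand$j[k]]) {
        keep[k] <- TRUE
        used_a[cand$i[k]] <- TRUE
        used_b[cand$j[k]] <- TRUE
      }
    }
    matched <- cand[keep, , drop = FALSE]
  }
  if (is.null(matched) || !nrow(matched)) {
    shared <- data.frame(chrom = character(), start_a = numeric(),
                         end_a = numeric(), start_b = numeric(),
                         end_b = numeric(), intersection = numeric(),
                         stringsAsFactors = FALSE)
    inter_total <- 0
    idx_a <- idx_b <- integer()
  } else {
    shared <- data.frame(chrom = set_a$chrom[matched$i],
                         start_a = set_a$start[matched$i],
                         end_a = set_a$end[matched$i],
                         start_b = set_b$start[matched$j],
                         end_b = set_b$end[matched$j],
                         intersection = matched$inter,
                         stringsAsFactors = FALSE)
    inter_total <- sum(matched$inter)
    idx_a <- matched$i; idx_b <- matched$j
  }
  both <- rbind(set_a[, c("chrom", "start", "end")],
                set_b[, c("chrom", "start", "end")])
  uni <- union_length(both)
  structure(list(
    shared = shared,
    private_a = set_a[setdiff(seq_len(na), idx_a), , drop = FALSE],
    private_b = set_b[setdiff(seq_len(nb), idx_b), , drop = FALSE],
    jaccard = if (uni > 0) inter_total / uni else NA_real_
  ), class = "segment_set_comparison")
}

#' Minimal common region across samples
#'
#' Breakpoint-sweep intersection: over all elementary intervals induced by the
#' input breakpoints, finds the region supported by the greatest number of
#' distinct samples (requiring at least `min_support`); adjacent elementary
#' intervals with the same maximal support are merged; ties are broken by
#' taking the leftmost region (first chromosome in sorted order).
#'
#' @param interval_sets list (one element per sample) of data.frames with
#'   `chrom`, `start`, `end`.
#' @param min_support minimum number of supporting samples (default 2).
#' @return data.frame with `chrom`, `start`, `end`, `support` (0 rows when no
#'   region reaches `min_support`).
#' @export
minimal_common_region <- function(interval_sets, min_support = 2) {
  all_iv <- do.call(rbind, lapply(seq_along(interval_sets), function(s) {
    df <- interval_sets[[s]]
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(sample = s, chrom = df$chrom, start = df$start, end = df$end,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      support = integer(), stringsAsFactors = FALSE)
  if (is.null(all_iv) || !nrow(all_iv)) return(empty)
  best <- empty
  for (ch in sort(unique(all_iv$chrom))) {
    s <- all_iv[all_iv$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(s$start, s$end + 1)))
    if (length(bp) < 2) next
    starts <- bp[-length(bp)]
    ends <- bp[-1] - 1
    support <- vapply(seq_along(starts), function(k) {
      covering <- s$start <= starts[k] & s$end >= ends[k]
      length(unique(s$sample[covering]))
    }, integer(1))
    ok <- support >= min_support
    if (!any(ok)) next
    top <- max(support[ok])
    runs <- rle(support == top & ok)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1
    first <- which(runs$values)[1]
    region <- data.frame(chrom = ch, start = starts[idx_start[first]],
                         end = ends[idx_end[first]], support = top,
                         stringsAsFactors = FALSE)
    if (!nrow(best) || top > best$support) best <- region
  }
  rownames(best) <- NULL
  best
}

#' Rank genes by copy-number event prevalence
#'
#' A gene scores the number of distinct patients with at least one sample in
#' `group` whose gene-level call shows the event (`gain_or_amp`: category Gain
#' or Amplification; `loss_or_del`: category Loss or Deletion) — a gene is
#' counted at most once per patient per tumor group, so patients with many
#' recurrences cannot skew the ranking. Descending by score, ties broken
#' lexicographically by gene symbol.
#'
#' @param gene_calls data.frame from [cohort_gene_cn()] (columns gene,
#'   category, patient_id, group).
#' @param event `"gain_or_amp"` or `"loss_or_del"`.
#' @param group `"primary"` or `"recurrent"`.
#' @return data.frame with `gene` and `score`, ready for [write_rnk()].
#' @export
rank_genes_by_cn_event <- function(gene_calls, event = c("gain_or_amp", "loss_or_del"),
                                   group) {
  event <- match.arg(event)
  if (!group %in% c("primary", "recurrent")) {
    stop_lohscape("unknown group label: ", group)
  }
  empty <- data.frame(gene = character(), score = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(gene_calls)) return(empty)
  cats <- if (event == "gain_or_amp") c("Gain", "Amplification") else c("Loss", "Deletion")
  d <- gene_calls[gene_calls$group == group &
                    !is.na(gene_calls$category) &
                    gene_calls$category %in% cats, , drop = FALSE]
  if (!nrow(d)) return(empty)
  agg <- aggregate(patient_id ~ gene, data = d,
                   FUN = function(p) length(unique(p)))
  names(agg)[2] <- "score"
  agg <- agg[order(-agg$score, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
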