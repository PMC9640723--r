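#' Two-isoform usage quantification
#'
#' Computes isoform fractions (each isoform's expression divided by total
#' gene expression) and a per-sample dominance call: `both` when both
#' fractions are at least `both_threshold`; otherwise `short` or `long`
#' according to the larger fraction; `none` when total expression is zero
#' (fractions undefined, reported NA).
#'
#' @param counts data.frame with `sample_id`, `isoform_long`,
#'   `isoform_short` (non-negative).
#' @param both_threshold minimum minor-isoform fraction for a `both` call
#'   (default 0.2); a sample is considered to express a single isoform
#'   exclusively when the other isoform's fraction is below this threshold.
#' @return data.frame with `total`, `if_short`, `if_long`, `dominance`
#'   columns added.
#' @export
compute_usage <- function(counts, both_threshold = 0.2) {
  need <- c("sample_id", "isoform_long", "isoform_short")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$isoform_long < 0 | counts$isoform_short < 0)) {
    stop_lohscape("isoform counts must be >= 0")
  }
  total <- counts$isoform_long + counts$isoform_short
  if_short <- ifelse(total > 0, counts$isoform_short / total, NA_real_)
  if_long <- ifelse(total > 0, 1 - if_short, NA_real_)
  dominance <- ifelse(total == 0, "none",
                      ifelse(pmin(if_short, if_long) >= both_threshold, "both",
                             ifelse(if_short > if_long, "short", "long")))
  out <- counts
  out$total <- total
  out$if_short <- if_short
  out$if_long <- if_long
  out$dominance <- dominance
  out
}

#' Patient-level short-isoform exposure
#'
#' A patient is exposed when any of their tumors (primary or recurrent)
#' expresses the short isoform — dominance `short` or `both`. Patients whose
#' tumors all have zero total expression have undefined exposure (NA, with a
#' warning) and should be excluded from survival models.
#'
#' @param usage usage table from [compute_usage()] covering one patient's
#'   tumors.
#' @return single logical (or NA).
#' @export
exposure_by_patient <- function(usage) {
  if (all(usage$total == 0)) {
    warning("all tumors have zero isoform expression; exposure undefined")
    return(NA)
  }
  any(usage$dominance %in% c("short", "both"))
}

#' Mantel-Haenszel chi-squared trend test with continuity correction
#'
#' Stratified 2x2 association test (1 df). Strata are 2x2 tables, e.g.
#' short-vs-long isoform dominance by case status across the normal, primary
#' and recurrence groups. Uses the standard Mantel-Haenszel statistic
#' `(|sum(a_k - E_k)| - 1/2)^2 / sum(V_k)` with the hypergeometric variance
#' `V_k = n1k n2k m1k m2k / (Nk^2 (Nk - 1))`; with a single stratum this
#' equals the Yates-corrected Pearson chi-square times `(N-1)/N`. Strata with
#' a degenerate margin contribute nothing; all-degenerate input is an error.
#'
#' @param tables 2x2xK array or list of 2x2 matrices.
#' @return list with `statistic`, `p_value`, `df` (= 1), `n_strata`.
#' @export
mantel_haenszel_trend <- function(tables) {
  if (is.array(tables) && length(dim(tables)) == 3) {
    tables <- lapply(seq_len(dim(tables)[3]), function(k) tables[, , k])
  }
  if (is.matrix(tables)) tables <- list(tables)
  stopifnot(all(vapply(tables, function(t) all(dim(t) == c(2, 2)), logical(1))))
  num <- 0
  var_sum <- 0
  used <- 0L
  for (t in tables) {
    n1 <- sum(t[1, ]); n2 <- sum(t[2, ])
    m1 <- sum(t[, 1]); m2 <- sum(t[, 2])
    N <- sum(t)
    if (N < 2 || n1 == 0 || n2 == 0 || m1 == 0 || m2 == 0) next
    num <- num + t[1, 1] - n1 * m1 / N
    var_sum <- var_sum + n1 * n2 * m1 * m2 / (N^2 * (N - 1))
    used <- used + 1L
  }
  if (used == 0 || var_sum == 0) {
    stop_lohscape("all strata have degenerate margins")
  }
  stat <- (max(abs(num) - 0.5, 0))^2 / var_sum
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, n_strata = used)
}

#' Isoform switch detection between two groups
#'
#' Usage-based two-group test: dIF is the difference in mean short-isoform
#' fraction (group B minus group A); significance from a two-sided Wilcoxon
#' rank-sum test on per-sample fractions. A switch is flagged when
#' `|dIF| >= dif_threshold` and the (BH-adjusted, when several genes are
#' tested together via [isoform_switch_table()]) p-value is below `alpha`.
#'
#' @param if_a,if_b numeric vectors of per-sample short-isoform fractions
#'   (NAs dropped); each group needs >= 3 defined samples.
#' @param dif_threshold effect-size gate on |dIF| (default 0.1).
#' @param alpha significance level (default 0.05).
#' @return list with `dif`, `p_value`, `switch`.
#' @export
detect_isoform_switch <- function(if_a, if_b, dif_threshold = 0.1,
                                  alpha = 0.05) {
  if_a <- if_a[!is.na(if_a)]
  if_b <- if_b[!is.na(if_b)]
  if (length(if_a) < 3 || length(if_b) < 3) {
    stop_lohscape("need >= 3 samples with defined isoform fraction per group")
  }
  dif <- mean(if_b) - mean(if_a)
  p <- suppressWarnings(wilcox.test(if_a, if_b, exact = NULL)$p.value)
  if (is.na(p)) p <- 1  # identical constant groups
  list(dif = dif, p_value = p,
       switch = abs(dif) >= dif_threshold && p < alpha)
}

#' Multi-gene isoform switch table with BH correction
#'
#' Runs [detect_isoform_switch()] per gene and applies Benjamini-Hochberg
#' correction across genes; the switch flag then uses q < `alpha`.
#'
#' @param usage_by_gene named list; each element a list with elements `a` and
#'   `b` (vectors of short-isoform fractions for the two groups).
#' @inheritParams detect_isoform_switch
#' @return data.frame: gene, dif, p_value, q_value, switch.
#' @export
isoform_switch_table <- function(usage_by_gene, dif_threshold = 0.1,
                                 alpha = 0.05) {
  rows <- lapply(names(usage_by_gene), function(g) {
    r <- detect_isoform_switch(usage_by_gene[[g]]$a, usage_by_gene[[g]]$b,
                               dif_threshold, alpha)
    data.frame(gene = g, dif = r$dif, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$switch <- abs(out$dif) >= dif_threshold & out$q_value < alpha
  out
}

#' Cox proportional-hazards fit for isoform exposure
#'
#' Partial-likelihood Cox model (Efron tie handling) of overall survival on
#' short-isoform exposure plus optional covariates; per-term hazard ratios
#' with Wald 95% CIs (`exp(coef +/- 1.96 SE)`) and Wald p-values. The breast
#' specification in this workflow is univariate exposure; the ovarian one
#' adds recurrent status as a covariate.
#'
#' @param records data.frame with `os_months`, `event`, and the covariate
#'   columns named in `covariates`.
#' @param covariates character vector of covariate column names; the first is
#'   conventionally the exposure.
#' @return data.frame: term, coef, se, hr, ci_lower, ci_upper, p_value.
#' @export
fit_cox <- function(records, covariates = "exposure") {
  stopifnot(all(c("os_months", "event") %in% names(records)),
            all(covariates %in% names(records)))
  records <- records[complete.cases(records[, c("os_months", "event",
                                                covariates)]), ]
  fml <- stats::as.formula(paste("survival::Surv(os_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  if (!is.null(fit$info) && !is.null(fit$info$convergence) &&
      fit$info$convergence != 0) {
    stop_lohscape("Cox model did not converge")
  }
  s <- summary(fit)
  co <- s$coefficients
  data.frame(term = rownames(co), coef = co[, "coef"],
             se = co[, "se(coef)"], hr = exp(co[, "coef"]),
             ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             p_value = co[, "Pr(>|z|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier median survival by exposure arm
#'
#' Median overall survival per arm with log-log 95% confidence intervals;
#' when a curve never crosses 0.5 the median and/or CI bound is NA
#' (open-ended).
#'
#' @param records data.frame with `os_months`, `event` and the grouping
#'   column `arm`.
#' @param arm name of the grouping column (default "exposure").
#' @return data.frame: arm, n, events, median, ci_lower, ci_upper.
#' @export
km_medians <- function(records, arm = "exposure") {
  stopifnot(all(c("os_months", "event", arm) %in% names(records)))
  fml <- stats::as.formula(paste("survival::Surv(os_months, event) ~", arm))
  fit <- survival::survfit(fml, data = records, conf.type = "log-log")
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list("all", names(tab)))
  data.frame(arm = rownames(tab), n = tab[, "records"],
             events = tab[, "events"], median = tab[, "median"],
             ci_lower = tab[, "0.95LCL"], ci_upper = tab[, "0.95UCL"],
             row.names = NULL, stringsAsFactors = FALSE)
}
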