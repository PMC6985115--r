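# Molecular response / MRD classification and the clinical-association
# statistics: contingency analyses, concordance with pathologic
# regression, Kaplan-Meier/log-rank survival comparisons with an O/E
# hazard ratio, and ctDNA lead time to clinical recurrence.

#' Classify molecular response from longitudinal ctDNA statuses
#'
#' Per patient, from baseline and preoperative detection:
#' `cleared` (baseline-positive, preoperative-negative), `persistent`
#' (positive at both), `emergent` (baseline-negative but
#' preoperative-positive), `never_detected` otherwise. The postoperative
#' status is carried through and may be missing (no postoperative
#' sample).
#'
#' @param statuses [ctdna_status()] table covering at least the baseline
#'   and preoperative timepoints for every patient.
#' @return data.frame with `patient_id`, `baseline_detected`,
#'   `preop_detected`, `postop_detected` (NA when unsampled), `category`.
#' @export
classify_molecular_response <- function(statuses) {
  pick <- function(pid, tp) {
    row <- statuses[statuses$patient_id == pid & statuses$timepoint == tp, ,
                    drop = FALSE]
    if (nrow(row) == 0) NA else row$detected[1]
  }
  out <- lapply(unique(statuses$patient_id), function(pid) {
    base <- pick(pid, "baseline")
    pre <- pick(pid, "preoperative")
    post <- pick(pid, "postoperative")
    if (is.na(base) || is.na(pre))
      validation_stop(paste0("patient ", pid,
                             " lacks a baseline or preoperative status"))
    category <- if (base && !pre) "cleared" else
      if (base && pre) "persistent" else
        if (!base && pre) "emergent" else "never_detected"
    data.frame(patient_id = pid, baseline_detected = base,
               preop_detected = pre, postop_detected = post,
               category = category, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric enumeration with fixed margins (two-sided: all
#' tables whose point probability does not exceed the observed one). The
#' odds ratio is the cross-product, with a 0.5 continuity correction
#' applied to all cells when any cell is zero.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `table`, `p_two_sided`, `odds_ratio`.
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    validation_stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    validation_stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    validation_stop("zero margin in contingency table")
  ft <- stats::fisher.test(table)
  or_tab <- if (any(table == 0)) table + 0.5 else table
  list(table = table, p_two_sided = unname(ft$p.value),
       odds_ratio = (or_tab[1, 1] * or_tab[2, 2]) /
         (or_tab[1, 2] * or_tab[2, 1]))
}

#' Concordance between preoperative ctDNA and pathologic regression
#'
#' A resected patient is concordant when pathologic response and ctDNA
#' agree: any regression (TRG 1-4) with undetected ctDNA, or no
#' regression (TRG 5) with detected ctDNA. The accompanying contingency
#' test dichotomizes TRG 1-4 vs TRG 5 by default (the dichotomy under
#' which concordance is defined); TRG 1-2 vs 3-5 (responders vs the
#' rest) is available as an option.
#'
#' @param clinical clinical table (TRG present for resected patients).
#' @param statuses [ctdna_status()] rows for the timepoint of interest
#'   (typically preoperative).
#' @param dichotomy `"trg1_4_vs_5"` (default) or `"trg1_2_vs_3_5"` for
#'   the contingency table.
#' @return list with `n_concordant`, `n_total`, `fraction`, and
#'   `contingency` (a [fisher_exact_two_sided()] result). Patients with a
#'   status but no TRG are excluded with a warning.
#' @export
concordance_with_trg <- function(clinical, statuses,
                                 dichotomy = c("trg1_4_vs_5",
                                               "trg1_2_vs_3_5")) {
  dichotomy <- match.arg(dichotomy)
  merged <- merge(statuses, clinical[, c("patient_id", "trg")],
                  by = "patient_id")
  drop <- is.na(merged$trg)
  if (any(drop)) {
    warning(sum(drop), " patient(s) with a ctDNA status but no TRG ",
            "excluded from concordance", call. = FALSE)
    merged <- merged[!drop, , drop = FALSE]
  }
  concordant <- (merged$trg <= 4 & !merged$detected) |
    (merged$trg == 5 & merged$detected)
  cut <- if (dichotomy == "trg1_4_vs_5") 4 else 2
  tab <- matrix(c(sum(merged$trg <= cut & merged$detected),
                  sum(merged$trg <= cut & !merged$detected),
                  sum(merged$trg > cut & merged$detected),
                  sum(merged$trg > cut & !merged$detected)),
                nrow = 2, byrow = TRUE,
                dimnames = list(trg = c("low", "high"),
                                ctdna = c("detected", "not_detected")))
  list(n_concordant = sum(concordant), n_total = nrow(merged),
       fraction = sum(concordant) / nrow(merged),
       contingency = fisher_exact_two_sided(tab))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times.
#' @param events logical/0-1 event indicators.
#' @return list with `time`, `surv` (the step curve), `median` (first
#'   time the curve reaches 0.5 or below; NA when never reached, i.e.
#'   median not reached).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) validation_stop("empty survival input")
  if (any(times < 0)) validation_stop("negative survival time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       median = med)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: at each event time the observed minus
#' expected events in group 1 under the hypergeometric null, summed;
#' chi-square with 1 df.
#'
#' @param times,events follow-up times and event indicators.
#' @param group two-level grouping vector.
#' @return list with `chi2`, `p`, `observed`, `expected` (per group,
#'   in level order), `groups`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    validation_stop("log-rank test needs exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp),
       groups = levels(droplevels(group)))
}

#' O/E (Mantel-Haenszel-style) hazard ratio with 95% CI
#'
#' `HR = (O1/E1) / (O0/E0)` for the comparison level versus the
#' reference, with observed and expected event counts from the log-rank
#' risk tables; the log-HR variance is approximated by `1/E1 + 1/E0`.
#' Undefined (all-NA) when either expected count is zero or a group has
#' no events.
#'
#' @inheritParams logrank_test
#' @param ref reference group level (default: first factor level).
#' @return list with `hr`, `ci_low`, `ci_high`, `ref`.
#' @export
hazard_ratio_oe <- function(times, events, group, ref = NULL) {
  group <- as.factor(group)
  lr <- logrank_test(times, events, group)
  lv <- lr$groups
  if (is.null(ref)) ref <- lv[1]
  i_ref <- match(ref, lv)
  i_cmp <- setdiff(seq_along(lv), i_ref)
  O <- lr$observed
  E <- lr$expected
  if (any(E[c(i_ref, i_cmp)] == 0) || any(O[c(i_ref, i_cmp)] == 0)) {
    warning("hazard ratio undefined: a group has no (expected) events",
            call. = FALSE)
    return(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                ref = ref))
  }
  log_hr <- log((O[i_cmp] / E[i_cmp]) / (O[i_ref] / E[i_ref]))
  se <- sqrt(1 / E[i_cmp] + 1 / E[i_ref])
  list(hr = exp(log_hr), ci_low = exp(log_hr - 1.96 * se),
       ci_high = exp(log_hr + 1.96 * se), ref = ref)
}

#' Full two-group survival comparison
#'
#' Bundles the log-rank test, the O/E hazard ratio, and per-group KM
#' medians into one report row.
#'
#' @inheritParams hazard_ratio_oe
#' @return list with `logrank` ([logrank_test()]), `hazard`
#'   ([hazard_ratio_oe()]), and `median_by_group` (named, NA = not
#'   reached).
#' @export
survival_comparison <- function(times, events, group, ref = NULL) {
  group <- as.factor(group)
  med <- vapply(levels(droplevels(group)), function(g)
    km_estimate(times[group == g], events[group == g])$median %||% NA_real_,
    numeric(1))
  list(logrank = logrank_test(times, events, group),
       hazard = hazard_ratio_oe(times, events, group, ref),
       median_by_group = med)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' ctDNA lead time over clinical recurrence
#'
#' For patients with postoperative ctDNA detected and an observed
#' clinical recurrence, lead time is the recurrence time minus the
#' postoperative sample (molecular detection) time, in months.
#'
#' @param statuses postoperative [ctdna_status()] rows.
#' @param clinical clinical table with `recurrence_months` and
#'   `postop_sample_months`.
#' @return list with `per_patient` (patient_id, lead_months) and
#'   `median_lead_months` (NA when no patient is eligible).
#' @export
lead_time_months <- function(statuses, clinical) {
  post <- statuses[statuses$timepoint == "postoperative" & statuses$detected, ,
                   drop = FALSE]
  merged <- merge(post, clinical, by = "patient_id")
  merged <- merged[!is.na(merged$recurrence_months) &
                     !is.na(merged$postop_sample_months), , drop = FALSE]
  lead <- merged$recurrence_months - merged$postop_sample_months
  list(per_patient = data.frame(patient_id = merged$patient_id,
                                lead_months = lead,
                                stringsAsFactors = FALSE),
       median_lead_months = if (length(lead) > 0) stats::median(lead) else
         NA_real_)
}

## ---- thin wrappers over standard report statistics ----------------------

#' Standard report statistics
#'
#' Thin wrappers used by the report tables: Wilcoxon rank-sum and
#' Kruskal-Wallis for continuous comparisons, Pearson correlation, and
#' the chi-square independence test. All two-sided.
#'
#' @param x,y numeric vectors.
#' @name report_stats
#' @return the underlying `htest` statistic and p-value as a list.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  ht <- stats::wilcox.test(x, y)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @param values numeric vector; `groups` a grouping vector.
#' @rdname report_stats
#' @export
kruskal_wallis <- function(values, groups) {
  ht <- stats::kruskal.test(values, as.factor(groups))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @rdname report_stats
#' @export
pearson_correlation <- function(x, y) {
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' @param table contingency matrix.
#' @rdname report_stats
#' @export
chisq_independence <- function(table) {
  ht <- suppressWarnings(stats::chisq.test(table))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
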