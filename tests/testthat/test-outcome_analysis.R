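status_row <- function(pid, tp, det) {
  data.frame(patient_id = pid, timepoint = tp, detected = det,
             n_tumor_variants = as.integer(det), max_maf_percent = 0,
             stringsAsFactors = FALSE)
}

test_that("molecular response categories follow the timeline", {
  st <- rbind(status_row("A", "baseline", TRUE),
              status_row("A", "preoperative", FALSE),
              status_row("B", "baseline", FALSE),
              status_row("B", "preoperative", TRUE),
              status_row("C", "baseline", FALSE),
              status_row("C", "preoperative", FALSE),
              status_row("D", "baseline", TRUE),
              status_row("D", "preoperative", TRUE),
              status_row("D", "postoperative", TRUE))
  mr <- classify_molecular_response(st)
  expect_equal(mr$category[match(c("A", "B", "C", "D"), mr$patient_id)],
               c("cleared", "emergent", "never_detected", "persistent"))
  expect_true(is.na(mr$postop_detected[mr$patient_id == "A"]))
  expect_true(mr$postop_detected[mr$patient_id == "D"])
  expect_error(classify_molecular_response(status_row("E", "baseline", TRUE)),
               class = "ctdnamrd_validation_error")
})

test_that("Fisher's exact p matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_two_sided(matrix(5, 2, 2))$p_two_sided, 1)
  # 0-of-7 vs 16-of-36: P(0)+P(6)+P(7) of Hypergeom(N=43, K=16, n=7)
  t1 <- matrix(c(0, 7, 16, 20), 2, byrow = TRUE)
  r1 <- fisher_exact_two_sided(t1)
  expect_equal(r1$p_two_sided, 0.03462271, tolerance = 1e-6)
  expect_equal(r1$p_two_sided, fisher_enumeration_oracle(t1))
  # the preoperative regression-vs-ctDNA table rounds to 0.03
  t2 <- matrix(c(6, 20, 10, 7), 2, byrow = TRUE)
  r2 <- fisher_exact_two_sided(t2)
  expect_equal(round(r2$p_two_sided, 2), 0.03)
  expect_equal(r2$p_two_sided, fisher_enumeration_oracle(t2),
               tolerance = 1e-9)

  set.seed(19)
  for (i in 1:100) {
    tab <- matrix(rpois(4, sample(1:15, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_sided(tab)$p_two_sided,
                 fisher_enumeration_oracle(tab), tolerance = 1e-9)
  }
  expect_error(fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2,
                                             byrow = TRUE)),
               class = "ctdnamrd_validation_error")
  # continuity-corrected odds ratio when a cell is empty
  expect_equal(fisher_exact_two_sided(t1)$odds_ratio,
               (0.5 * 20.5) / (7.5 * 16.5))
})

test_that("TRG concordance reproduces the printed cohort strata", {
  # 7 TRG1-2 patients all ctDNA-negative; 19 TRG3-4 with 13 negative;
  # 17 TRG5 with 10 positive
  clin <- data.frame(
    patient_id = sprintf("G%02d", 1:43),
    trg = c(rep(1:2, c(3, 4)), rep(3:4, c(10, 9)), rep(5, 17)))
  det <- c(rep(FALSE, 7), rep(TRUE, 6), rep(FALSE, 13), rep(TRUE, 10),
           rep(FALSE, 7))
  st <- do.call(rbind, lapply(1:43, function(i)
    status_row(clin$patient_id[i], "preoperative", det[i])))
  conc <- concordance_with_trg(clin, st)
  expect_equal(conc$n_concordant, 30)
  expect_equal(conc$n_total, 43)
  expect_equal(round(100 * conc$fraction), 70)
  expect_equal(round(conc$contingency$p_two_sided, 2), 0.03)
  # the responder dichotomy also lands at 0.03 on this cohort
  conc2 <- concordance_with_trg(clin, st, dichotomy = "trg1_2_vs_3_5")
  expect_equal(round(conc2$contingency$p_two_sided, 2), 0.03)

  # a status without a TRG is excluded with a warning
  clin_na <- clin
  clin_na$trg[1] <- NA
  expect_warning(conc3 <- concordance_with_trg(clin_na, st), "TRG")
  expect_equal(conc3$n_total, 42)
})

test_that("KM estimate matches the hand product-limit", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  expect_true(is.na(km_estimate(c(5, 6, 7), rep(FALSE, 3))$median))
  km1 <- km_estimate(5, TRUE)
  expect_equal(km1$surv, 0)
  expect_equal(km1$median, 5)
  # curve is non-increasing and starts from 1
  set.seed(12)
  km2 <- km_estimate(rexp(40, 0.1), runif(40) < 0.7)
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_lte(max(km2$surv), 1)
  expect_error(km_estimate(numeric(0), logical(0)),
               class = "ctdnamrd_validation_error")
})

test_that("log-rank and O/E hazard ratio match hand-tabulated risk sets", {
  # identical groups carry no signal
  ident <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6),
                        rep(c("a", "b"), each = 3))
  expect_equal(ident$chi2, 0, tolerance = 1e-12)
  expect_equal(ident$p, 1)
  expect_equal(hazard_ratio_oe(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6),
                               rep(c("a", "b"), each = 3))$hr, 1)

  # hand risk-table: A events at 1,2; B events at 10,11 ->
  # O_A=2, E_A=5/6, V=0.25+2/9, chi2=(7/6)^2/(17/36)
  lr <- logrank_test(c(1, 2, 10, 11), rep(TRUE, 4), c("A", "A", "B", "B"))
  expect_equal(lr$chi2, (7 / 6)^2 / (17 / 36), tolerance = 1e-9)
  expect_equal(lr$p, stats::pchisq((7 / 6)^2 / (17 / 36), 1,
                                   lower.tail = FALSE))

  # 6-subject worked example, hand-tabulated over 4 event times
  t6 <- c(2, 4, 6, 1, 3, 5)
  e6 <- c(1, 1, 0, 1, 0, 1)
  g6 <- rep(c("X", "Y"), each = 3)
  lr6 <- logrank_test(t6, e6, g6)
  expect_equal(lr6$observed, c(2, 2))
  expect_equal(lr6$expected, c(34 / 15, 26 / 15), tolerance = 1e-9)
  expect_equal(lr6$chi2, (2 - 34 / 15)^2 /
                 (0.25 + 0.24 + 2 / 9 + 0.25), tolerance = 1e-9)
  hr6 <- hazard_ratio_oe(t6, e6, g6, ref = "X")
  hr_hand <- (2 / (26 / 15)) / (2 / (34 / 15))
  se_hand <- sqrt(15 / 26 + 15 / 34)
  expect_equal(hr6$hr, hr_hand, tolerance = 1e-9)
  expect_equal(hr6$ci_low, hr_hand * exp(-1.96 * se_hand), tolerance = 1e-9)
  expect_equal(hr6$ci_high, hr_hand * exp(1.96 * se_hand), tolerance = 1e-9)

  # degenerate: a group without events has no defined hazard ratio
  expect_warning(
    hr_na <- hazard_ratio_oe(c(1, 2, 10, 11), c(1, 1, 0, 0),
                             c("A", "A", "B", "B")),
    "undefined")
  expect_true(is.na(hr_na$hr))
  expect_error(logrank_test(1:3, rep(TRUE, 3), rep("A", 3)),
               class = "ctdnamrd_validation_error")
})

test_that("log-rank has power against a strong hazard contrast", {
  set.seed(55)
  hits <- vapply(1:100, function(i) {
    g <- rep(c("pos", "neg"), each = 50)
    t <- ifelse(g == "pos", rexp(100, 0.25), rexp(100, 0.05))
    e <- t < 48
    t <- pmin(t, 48)
    logrank_test(t, e, g)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("lead time is recurrence minus molecular detection time", {
  st <- status_row("A", "postoperative", TRUE)
  clin <- data.frame(patient_id = "A", recurrence_months = 10.2,
                     postop_sample_months = 1.3)
  lt <- lead_time_months(st, clin)
  expect_equal(lt$median_lead_months, 8.9)

  clin0 <- transform(clin, recurrence_months = 1.3)
  expect_equal(lead_time_months(st, clin0)$median_lead_months, 0)

  none <- status_row("A", "postoperative", FALSE)
  expect_true(is.na(lead_time_months(none, clin)$median_lead_months))
})

test_that("report-statistic wrappers run two-sided on toy data", {
  w <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_lt(w$p, 0.05)
  k <- kruskal_wallis(c(1, 2, 3, 10, 11, 12, 20, 21, 22),
                      rep(letters[1:3], each = 3))
  expect_lt(k$p, 0.05)
  r <- pearson_correlation(1:10, (1:10) * 2 + 1)
  expect_equal(r$r, 1)
  x2 <- chisq_independence(matrix(c(20, 5, 5, 20), 2))
  expect_lt(x2$p, 0.01)
})
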