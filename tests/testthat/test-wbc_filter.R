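cfg <- pipeline_config()

called_row <- function(...) {
  calls <- call_candidates(make_obs(...), NULL, cfg)
  stopifnot(calls$call_status == "called")
  calls
}

test_that("WBC subtraction routes on a single altered distinct read", {
  cf <- called_row(k_alt = 30L)
  wbc1 <- make_obs(compartment = "WBC", k_alt = 1L, n_distinct = 28000L)
  part <- subtract_wbc(cf, wbc1, cfg)
  expect_equal(nrow(part$hematopoietic), 1)
  expect_equal(nrow(part$tumor_specific), 0)

  wbc0 <- transform(wbc1, k_alt = 0L)
  part <- subtract_wbc(cf, wbc0, cfg)
  expect_equal(nrow(part$tumor_specific), 1)

  # missing WBC control: everything kept, with a warning
  expect_warning(part <- subtract_wbc(cf, wbc0[0, ], cfg), "WBC")
  expect_equal(nrow(part$tumor_specific), 1)

  expect_error(subtract_wbc(cf, transform(wbc1, patient_id = "P9"), cfg),
               class = "ctdnamrd_validation_error")
  expect_error(subtract_wbc(cf, transform(wbc1, timepoint = "preoperative"),
                            cfg),
               class = "ctdnamrd_validation_error")
})

test_that("subtraction partitions called cfDNA variants exhaustively", {
  co <- simulate_cohort(simulation_config(40, seed = 3))
  calls <- call_cohort(co$observations)
  part <- subtract_wbc_cohort(calls)
  n_called_cf <- sum(calls$call_status == "called" &
                       calls$compartment == "cfDNA")
  expect_equal(nrow(part$tumor_specific) + nrow(part$hematopoietic),
               n_called_cf)
  expect_length(intersect(
    paste(part$tumor_specific$sample_id, variant_key(part$tumor_specific)),
    paste(part$hematopoietic$sample_id, variant_key(part$hematopoietic))), 0)
})

test_that("closed-form marginals match the quadrature oracle", {
  # no WBC coverage: the two models cannot be distinguished
  lm0 <- marginal_likelihood_closed_form(5, 1000, 0)
  expect_equal(lm0[["logml_tumor"]], lm0[["logml_hematopoietic"]])
  # empty data has probability one under both models
  lme <- marginal_likelihood_closed_form(0, 0, 0)
  expect_equal(unname(lme), c(0, 0))
  expect_error(marginal_likelihood_closed_form(10, 5, 0),
               class = "ctdnamrd_validation_error")

  grid <- expand.grid(k = c(0, 1, 3, 30), n = c(5000, 10000, 30000),
                      n_wbc = c(0, 5000, 10000, 30000))
  for (i in seq_len(nrow(grid))) {
    lm <- marginal_likelihood_closed_form(grid$k[i], grid$n[i],
                                          grid$n_wbc[i])
    # 6-significant-digit agreement on the marginal likelihood scale
    expect_lt(abs(lm[["logml_tumor"]] -
                    quadrature_logml_oracle(grid$k[i], grid$n[i], 0)),
              1e-6)
    expect_lt(abs(lm[["logml_hematopoietic"]] -
                    quadrature_logml_oracle(grid$k[i], grid$n[i],
                                            grid$n_wbc[i])),
              1e-6)
  }
  # counts up to 1e6 stay finite
  expect_true(all(is.finite(marginal_likelihood_closed_form(1000, 1e6,
                                                            1e6))))
})

test_that("Monte Carlo estimator is seeded, convergent and error-bounded", {
  m1 <- marginal_likelihood_monte_carlo(30, 10000, 10000, mc_draws = 1e4,
                                        seed = 101)
  m2 <- marginal_likelihood_monte_carlo(30, 10000, 10000, mc_draws = 1e4,
                                        seed = 101)
  expect_identical(m1, m2)
  expect_error(marginal_likelihood_monte_carlo(1, 10, 0, mc_draws = 50),
               class = "ctdnamrd_config_error")

  # empty data: every draw has probability exactly one under both models
  m0 <- marginal_likelihood_monte_carlo(0, 0, 0, mc_draws = 1000, seed = 1)
  expect_equal(m0$logml_tumor, 0)
  expect_equal(m0$logml_hematopoietic, 0)

  # posterior error within 3 MC s.e. of the closed form, shrinking s.e.
  closed <- tumor_origin_probability(30, 10000, 0, 10000, cfg)
  ses <- c()
  for (draws in c(1e3, 1e4, 1e5)) {
    mc <- marginal_likelihood_monte_carlo(30, 10000, 10000, mc_draws = draws,
                                          seed = 7)
    expect_lt(abs(mc$posterior_prob - closed$posterior_prob),
              3 * mc$posterior_se + 1e-12)
    ses <- c(ses, mc$posterior_se)
  }
  expect_true(all(diff(ses) < 0))
})

test_that("posterior tumor-origin probability behaves as the model dictates", {
  # any altered WBC read is fatal to the tumor model
  expect_equal(tumor_origin_probability(30, 10000, 2, 10000,
                                        cfg)$posterior_prob, 0)
  # no WBC coverage: prior odds 1 carry through
  expect_equal(tumor_origin_probability(30, 10000, 0, 0, cfg)$posterior_prob,
               0.5)
  # WBC-negative variant at depth: matches quadrature and exceeds 0.5
  p <- tumor_origin_probability(30, 10000, 0, 10000, cfg)
  oracle <- stats::plogis(quadrature_logml_oracle(30, 10000, 0) -
                            quadrature_logml_oracle(30, 10000, 10000))
  expect_equal(p$posterior_prob, oracle, tolerance = 1e-6)
  expect_gt(p$posterior_prob, 0.5)
  expect_equal(p$posterior_prob, p$bayes_factor / (1 + p$bayes_factor))

  # non-decreasing in n_wbc over a grid of (k_cf, n_cf)
  for (k in c(1, 3, 10, 30)) {
    for (n in c(5000, 30000)) {
      post <- vapply(c(0, 1000, 5000, 30000), function(nw)
        tumor_origin_probability(k, n, 0, nw, cfg)$posterior_prob,
        numeric(1))
      expect_true(all(diff(post) >= -1e-12))
      expect_equal(post[1], 0.5)
    }
  }
})

test_that("true tumor variants earn higher posteriors than CH escapees", {
  # shallow WBC depth so hematopoietic variants regularly escape the WBC
  # read-level filter and must be down-weighted by the model instead
  co <- simulate_cohort(simulation_config(150, seed = 6,
                                          wbc_coverage_mean = 500,
                                          ch_burden_age0 = 0.2,
                                          artifact_rate = 0))
  res <- run_mrd_pipeline(co$observations)
  ts <- res$tumor_specific
  truth <- co$truth$variants
  origin <- truth$origin[match(paste(ts$patient_id, variant_key(ts)),
                               paste(truth$patient_id,
                                     variant_key(truth)))]
  escapees <- ts$posterior_prob[origin == "hematopoietic"]
  tumor <- ts$posterior_prob[origin == "tumor"]
  expect_gt(length(escapees), 0)
  expect_gt(length(tumor), 10)
  expect_gt(mean(tumor), mean(escapees))
})

test_that("per-sample status reports detection and the highest MAF", {
  ts <- rbind(called_row(k_alt = 232L, n_distinct = 10000L),
              called_row(pos = 37845000L, gene = "ERBB2",
                         consequence = "frameshift", k_alt = 64L,
                         n_distinct = 10000L))
  idx <- data.frame(patient_id = "P1",
                    timepoint = c("baseline", "preoperative"))
  st <- ctdna_status(ts, idx, cfg)
  expect_equal(st$detected, c(TRUE, FALSE))
  expect_equal(st$max_maf_percent, c(2.32, 0))
  expect_equal(st$n_tumor_variants, c(2, 0))
})
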