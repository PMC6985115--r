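# Clonal-hematopoiesis subtraction and the Bayesian tumor-origin model.
#
# Hard filter: any called cfDNA variant seen in the matched baseline WBC
# sample at the level of a single distinct read is routed to the
# hematopoietic class. For variants with no altered WBC reads, two
# generative models are compared. Both treat the altered distinct-read
# counts as binomial in the distinct coverage with unknown allele
# fraction theta, with a Beta(2.4, 340) prior on theta_cfDNA (equivalent
# to 2.4 altered reads per 340 molecules, prior mean ~0.7%):
#
#   tumor-derived:  theta_WBC = 0, theta_cfDNA ~ Beta(2.4, 340)
#   hematopoietic:  theta_WBC = theta_cfDNA ~ Beta(2.4, 340)
#
# The marginal likelihood of each model integrates theta out; with prior
# odds 1 the posterior odds equal the Bayes factor and the posterior
# tumor-origin probability is PO / (1 + PO). The integral has a closed
# beta-binomial form (the default engine); the sampling estimator that
# averages the data probability over prior draws of theta is retained as
# an alternative engine and as a cross-check.

#' Subtract WBC-matched variants from cfDNA calls
#'
#' Partitions one patient's called cfDNA variants: a call is
#' hematopoietic when the identical variant key carries at least
#' `wbc_filter_min_reads` (default 1) altered distinct pairs in the
#' patient's baseline WBC sample, tumor-specific otherwise. The partition
#' is exhaustive and disjoint over the called rows.
#'
#' @param cfdna_calls calls for one patient's cfDNA samples (output of
#'   [call_candidates()]); only rows with `call_status == "called"` are
#'   partitioned.
#' @param wbc_baseline baseline WBC observations of the same patient (may
#'   be empty, in which case everything is tumor-specific and a warning
#'   notes the missing control).
#' @param config a [pipeline_config()].
#' @return list with data.frames `tumor_specific` and `hematopoietic`.
#' @export
subtract_wbc <- function(cfdna_calls, wbc_baseline,
                         config = pipeline_config()) {
  called <- cfdna_calls[cfdna_calls$call_status == "called", , drop = FALSE]
  if (nrow(wbc_baseline) > 0) {
    if (any(wbc_baseline$compartment != "WBC") ||
        any(wbc_baseline$timepoint != "baseline"))
      validation_stop("wbc_baseline must be baseline WBC observations")
    pats <- unique(c(called$patient_id, wbc_baseline$patient_id))
    if (length(pats) > 1)
      validation_stop("WBC table is from a different patient")
  } else if (nrow(called) > 0) {
    warning("no baseline WBC observations: all cfDNA calls kept as ",
            "tumor-specific", call. = FALSE)
  }
  wbc_pos <- wbc_baseline[wbc_baseline$k_alt >= config$wbc_filter_min_reads, ,
                          drop = FALSE]
  in_wbc <- variant_key(called) %in% variant_key(wbc_pos)
  list(tumor_specific = called[!in_wbc, , drop = FALSE],
       hematopoietic = called[in_wbc, , drop = FALSE])
}

#' Subtract WBC variants across a cohort
#'
#' @param calls cohort calls table from [call_cohort()] (both
#'   compartments).
#' @return list of row-bound `tumor_specific` and `hematopoietic` tables
#'   over all patients (cfDNA compartment only).
#' @rdname subtract_wbc
#' @export
subtract_wbc_cohort <- function(calls, config = pipeline_config()) {
  tumor <- list()
  hemat <- list()
  for (pid in unique(calls$patient_id)) {
    cf <- calls[calls$patient_id == pid & calls$compartment == "cfDNA", ,
                drop = FALSE]
    wbc <- calls[calls$patient_id == pid & calls$compartment == "WBC" &
                   calls$timepoint == "baseline", , drop = FALSE]
    part <- suppressWarnings(subtract_wbc(cf, wbc, config))
    tumor[[pid]] <- part$tumor_specific
    hemat[[pid]] <- part$hematopoietic
  }
  ts <- do.call(rbind, c(tumor, list(calls[0, ])))
  hm <- do.call(rbind, c(hemat, list(calls[0, ])))
  rownames(ts) <- rownames(hm) <- NULL
  list(tumor_specific = ts, hematopoietic = hm)
}

#' Closed-form log marginal likelihoods of the two origin models
#'
#' Integrating the binomial likelihood over the Beta(alpha, beta) prior
#' gives beta-binomial marginals. For a WBC-negative variant
#' (`k_wbc = 0`) with `k_cf` of `n_cf` altered cfDNA pairs and `n_wbc`
#' WBC coverage:
#' \deqn{\log m_T = \log C(n_{cf},k_{cf}) +
#'   \log B(k_{cf}+\alpha, n_{cf}-k_{cf}+\beta) - \log B(\alpha,\beta)}
#' \deqn{\log m_H = \log C(n_{cf},k_{cf}) +
#'   \log B(k_{cf}+\alpha, n_{cf}-k_{cf}+n_{wbc}+\beta) -
#'   \log B(\alpha,\beta)}
#' (the hematopoietic model spends the shared theta on the `n_wbc`
#' reference-only WBC draws as well). Computed entirely in log space;
#' finite for counts up to 1e6.
#'
#' @param k_cf altered distinct cfDNA pairs.
#' @param n_cf total distinct cfDNA pairs at the position.
#' @param n_wbc total distinct WBC pairs at the position (0 altered).
#' @param prior_alpha,prior_beta Beta prior shapes (defaults 2.4, 340).
#' @return named numeric vector `c(logml_tumor, logml_hematopoietic)`.
#' @export
marginal_likelihood_closed_form <- function(k_cf, n_cf, n_wbc,
                                            prior_alpha = 2.4,
                                            prior_beta = 340) {
  if (k_cf > n_cf) validation_stop("k_cf exceeds n_cf")
  if (min(k_cf, n_cf, n_wbc) < 0) validation_stop("negative count")
  base <- lchoose(n_cf, k_cf) - lbeta(prior_alpha, prior_beta)
  c(logml_tumor = base + lbeta(k_cf + prior_alpha,
                               n_cf - k_cf + prior_beta),
    logml_hematopoietic = base + lbeta(k_cf + prior_alpha,
                                       n_cf - k_cf + n_wbc + prior_beta))
}

#' Monte Carlo estimate of the origin-model marginal likelihoods
#'
#' Samples `mc_draws` allele fractions from the Beta prior, evaluates the
#' probability of the observed data under each model for every draw, and
#' averages: the ergodic mean approximates the marginal likelihood
#' unconditionally on theta. Per-draw probabilities for the two models
#' share the same theta draws, so the Bayes factor and the posterior
#' probability carry a (paired, delta-method) Monte Carlo standard error.
#' Deterministic for a fixed RNG state; pass `seed` to fix one locally.
#'
#' @inheritParams marginal_likelihood_closed_form
#' @param mc_draws number of prior draws (>= 100).
#' @param seed optional integer seed applied locally.
#' @return list with `logml_tumor`, `logml_hematopoietic`, their relative
#'   standard errors `rel_se_tumor`/`rel_se_hematopoietic`,
#'   `posterior_prob`, `posterior_se`, and `mc_draws`.
#' @export
marginal_likelihood_monte_carlo <- function(k_cf, n_cf, n_wbc,
                                            prior_alpha = 2.4,
                                            prior_beta = 340,
                                            mc_draws = 100000,
                                            seed = NULL) {
  if (k_cf > n_cf) validation_stop("k_cf exceeds n_cf")
  if (min(k_cf, n_cf, n_wbc) < 0) validation_stop("negative count")
  if (mc_draws < 100)
    config_stop("mc_draws below 100: estimator unusable")
  if (!is.null(seed)) set.seed(seed)
  theta <- stats::rbeta(mc_draws, prior_alpha, prior_beta)
  lp_t <- stats::dbinom(k_cf, n_cf, theta, log = TRUE)
  lp_h <- lp_t + n_wbc * log1p(-theta)
  scale <- max(lp_t)                      # lp_h <= lp_t always
  a <- exp(lp_t - scale)
  b <- exp(lp_h - scale)
  A <- mean(a)
  B <- mean(b)
  # delta method for f = A/(A+B), scale-invariant in (a, b)
  grad <- c(B, -A) / (A + B)^2
  covm <- stats::cov(cbind(a, b))
  post_var <- drop(t(grad) %*% covm %*% grad) / mc_draws
  list(logml_tumor = log(A) + scale,
       logml_hematopoietic = log(B) + scale,
       rel_se_tumor = stats::sd(a) / (A * sqrt(mc_draws)),
       rel_se_hematopoietic = stats::sd(b) / (B * sqrt(mc_draws)),
       posterior_prob = A / (A + B),
       posterior_se = sqrt(max(post_var, 0)),
       mc_draws = mc_draws)
}

#' Posterior probability that a variant is tumor derived
#'
#' Any altered WBC read (`k_wbc >= 1`) is fatal to the tumor-derived
#' model (which fixes theta_WBC at 0), so the posterior probability is
#' exactly 0 there. Otherwise the Bayes factor
#' `BF = m_T / m_H` is computed by the closed-form beta-binomial engine
#' (default) or the Monte Carlo engine, and with prior odds 1 the
#' posterior probability is `BF / (1 + BF)`. With no WBC coverage
#' (`n_wbc = 0`) the two marginals coincide and the probability is 0.5.
#'
#' @param k_cf,n_cf altered/total distinct cfDNA pairs.
#' @param k_wbc,n_wbc altered/total distinct WBC pairs.
#' @param config a [pipeline_config()] (prior shapes, `mc_draws`,
#'   `rng_seed`).
#' @param method `"closed_form"` (default) or `"monte_carlo"`.
#' @return one-row data.frame with `bayes_factor`, `posterior_prob`,
#'   `estimator`, `mc_draws`, `mc_std_error`.
#' @export
tumor_origin_probability <- function(k_cf, n_cf, k_wbc, n_wbc,
                                     config = pipeline_config(),
                                     method = c("closed_form",
                                                "monte_carlo")) {
  method <- match.arg(method)
  if (k_cf > n_cf || k_wbc > n_wbc) validation_stop("k exceeds n")
  if (min(k_cf, n_cf, k_wbc, n_wbc) < 0) validation_stop("negative count")
  if (k_wbc >= 1)
    return(data.frame(bayes_factor = 0, posterior_prob = 0,
                      estimator = "closed_form", mc_draws = NA_integer_,
                      mc_std_error = NA_real_))
  if (method == "closed_form") {
    lm <- marginal_likelihood_closed_form(k_cf, n_cf, n_wbc,
                                          config$prior_alpha,
                                          config$prior_beta)
    dlog <- lm[["logml_tumor"]] - lm[["logml_hematopoietic"]]
    data.frame(bayes_factor = exp(dlog),
               posterior_prob = stats::plogis(dlog),
               estimator = "closed_form", mc_draws = NA_integer_,
               mc_std_error = NA_real_)
  } else {
    mc <- marginal_likelihood_monte_carlo(k_cf, n_cf, n_wbc,
                                          config$prior_alpha,
                                          config$prior_beta,
                                          config$mc_draws,
                                          seed = config$rng_seed)
    data.frame(bayes_factor = exp(mc$logml_tumor - mc$logml_hematopoietic),
               posterior_prob = mc$posterior_prob,
               estimator = "monte_carlo", mc_draws = mc$mc_draws,
               mc_std_error = mc$posterior_se)
  }
}

#' Annotate tumor-specific calls with the origin posterior
#'
#' Applied after [subtract_wbc()], so every row has no altered WBC reads.
#' The WBC coverage `n_wbc` at a variant is the WBC distinct coverage at
#' that position when the WBC table carries a row there, the patient's
#' median WBC coverage otherwise, and 0 (posterior 0.5) when the patient
#' has no WBC rows at all.
#'
#' @param tumor_specific tumor-specific calls (one or more patients).
#' @param wbc_observations baseline WBC observation rows for the same
#'   patients.
#' @param config a [pipeline_config()].
#' @param method engine passed to [tumor_origin_probability()].
#' @return `tumor_specific` with appended `n_wbc`, `bayes_factor`,
#'   `posterior_prob` columns.
#' @export
annotate_tumor_origin <- function(tumor_specific, wbc_observations,
                                  config = pipeline_config(),
                                  method = "closed_form") {
  n <- nrow(tumor_specific)
  out <- tumor_specific
  out$n_wbc <- integer(n)
  out$bayes_factor <- numeric(n)
  out$posterior_prob <- numeric(n)
  if (n == 0) return(out)
  wkeys <- variant_key(wbc_observations)
  for (i in seq_len(n)) {
    pid <- tumor_specific$patient_id[i]
    pw <- wbc_observations[wbc_observations$patient_id == pid, , drop = FALSE]
    hit <- pw[variant_key(pw) == variant_key(tumor_specific[i, ]), ,
              drop = FALSE]
    n_wbc <- if (nrow(hit) > 0) hit$n_distinct[1] else
      if (nrow(pw) > 0) round(stats::median(pw$n_distinct)) else 0L
    assess <- tumor_origin_probability(tumor_specific$k_alt[i],
                                       tumor_specific$n_distinct[i],
                                       0L, n_wbc, config, method)
    out$n_wbc[i] <- n_wbc
    out$bayes_factor[i] <- assess$bayes_factor
    out$posterior_prob[i] <- assess$posterior_prob
  }
  out
}

#' Per-sample ctDNA detection status
#'
#' A (patient, timepoint) cfDNA sample is ctDNA-detected when at least
#' one tumor-specific call survives the WBC filter there (optionally also
#' requiring a minimum origin posterior via `config$p_min`).
#'
#' @param tumor_specific WBC-filtered calls (cohort-wide).
#' @param sample_index data.frame of the cfDNA samples to report, columns
#'   `patient_id`, `timepoint` (samples with zero calls must appear here
#'   to be reported as not detected).
#' @param config a [pipeline_config()].
#' @return data.frame with `patient_id`, `timepoint`, `detected`,
#'   `n_tumor_variants`, `max_maf_percent`.
#' @export
ctdna_status <- function(tumor_specific, sample_index,
                         config = pipeline_config()) {
  keep <- tumor_specific
  if (config$p_min > 0 && nrow(keep) > 0) {
    if (is.null(keep$posterior_prob))
      validation_stop("p_min > 0 requires posterior_prob annotation")
    keep <- keep[keep$posterior_prob >= config$p_min, , drop = FALSE]
  }
  idx <- unique(sample_index[, c("patient_id", "timepoint")])
  res <- lapply(seq_len(nrow(idx)), function(i) {
    sub <- keep[keep$patient_id == idx$patient_id[i] &
                  keep$timepoint == idx$timepoint[i], , drop = FALSE]
    data.frame(patient_id = idx$patient_id[i], timepoint = idx$timepoint[i],
               detected = nrow(sub) >= 1, n_tumor_variants = nrow(sub),
               max_maf_percent = if (nrow(sub) > 0)
                 max(100 * maf_fraction(sub$k_alt, sub$n_distinct)) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
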