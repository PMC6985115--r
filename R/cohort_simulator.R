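# Synthetic matched cfDNA/WBC cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# deep targeted sequencing (~30,000x distinct coverage), hematopoietic
# variants shared between WBC and cfDNA at the same underlying allele
# fraction at every timepoint, tumor-only cfDNA variants that may clear
# under preoperative therapy and after surgery, shorter tumor-derived
# fragment lengths, and recurrence/survival outcomes coupled to true
# postoperative residual disease. Ground-truth labels accompany every
# emitted row so parameter and origin recovery can be scored.

# genes of a gastric-cancer driver panel used to place synthetic variants;
# weights reflect which compartment's variants concentrate where
ch_panel <- data.frame(
  gene = c("DNMT3A", "TP53", "EGFR", "APC", "AR", "ATM", "MLH1"),
  chrom = c("chr2", "chr17", "chr7", "chr5", "chrX", "chr11", "chr3"),
  base = c(25450000, 7570000, 55080000, 112040000, 66760000, 108090000,
           37030000),
  weight = c(0.45, 0.29, 0.10, 0.06, 0.04, 0.03, 0.03),
  stringsAsFactors = FALSE)

tumor_panel <- data.frame(
  gene = c("TP53", "MYC", "PIK3CA", "KRAS", "HRAS", "BRAF", "ALK", "ATM",
           "KIT", "CDH1", "ERBB2", "ERBB4"),
  chrom = c("chr17", "chr8", "chr3", "chr12", "chr11", "chr7", "chr2",
            "chr11", "chr4", "chr16", "chr17", "chr2"),
  base = c(7570000, 128740000, 178860000, 25350000, 530000, 140410000,
           29190000, 108090000, 55520000, 68770000, 37840000, 212240000),
  weight = c(0.22, 0.15, 0.15, 0.11, 0.11, 0.11, 0.11, 0.11, 0.11, 0.07,
             0.05, 0.05),
  stringsAsFactors = FALSE)

callable_consequences <- c("missense", "nonsense", "frameshift", "splice")

#' Simulation configuration for synthetic matched cohorts
#'
#' Defaults describe the deep targeted-sequencing setting the pipeline is
#' built for; every knob is exposed so sensitivity studies can move one at
#' a time.
#'
#' \describe{
#'   \item{n_patients}{cohort size (required).}
#'   \item{coverage_mean}{mean distinct-read-pair coverage (Poisson,
#'     truncated at 1); default 30000.}
#'   \item{wbc_coverage_mean}{mean WBC distinct coverage when the WBC
#'     libraries are sequenced at a different depth; `NULL` (default)
#'     uses `coverage_mean`.}
#'   \item{ch_burden_age0, ch_rate_per_year}{the expected number of
#'     clonal-hematopoiesis (CH) variants per patient is
#'     `ch_burden_age0 * exp(ch_rate_per_year * age)`, a Poisson mean that
#'     grows exponentially with age; defaults 0.05 and 0.05/yr give ~1
#'     expected CH variant at age 60.}
#'   \item{ch_maf_log_mean, ch_maf_log_sd}{lognormal CH allele fraction,
#'     centered near 0.3\% MAF (defaults log(0.003), 0.9).}
#'   \item{tumor_maf_log_mean, tumor_maf_log_sd, tumor_maf_min}{lognormal
#'     tumor allele fraction truncated below at `tumor_maf_min` (default
#'     0.001, the 0.1\% scale at which a 30,000x assay detects reliably).}
#'   \item{tumor_variants_mean}{mean tumor variants per shedding patient
#'     (Poisson truncated at 1); default 2.}
#'   \item{shed_prob_intestinal, shed_prob_diffuse, shed_prob_other}{
#'     probability a tumor sheds detectable ctDNA at baseline, by Lauren
#'     subtype; intestinal tumors shed more often than diffuse ones
#'     (defaults 0.75 / 0.40 / 0.50).}
#'   \item{p_responder}{probability of pathologic response (TRG 1-2);
#'     default 0.3.}
#'   \item{clearance_prob_responder, clearance_prob_nonresponder}{
#'     probability ctDNA is eliminated by the preoperative timepoint
#'     (defaults 0.9 / 0.15).}
#'   \item{mrd_prob_persistent}{probability a patient with persistent
#'     preoperative ctDNA still has residual disease after surgery;
#'     default 0.6.}
#'   \item{frag_len_tumor_mean, frag_len_wt_mean, frag_len_sd}{fragment
#'     length model in bp; tumor-derived fragments are shorter (defaults
#'     145 / 167 / 25, the mononucleosomal mode).}
#'   \item{hazard_mrd_pos, hazard_mrd_neg}{monthly exponential recurrence
#'     hazards given true postoperative MRD status (defaults 0.08 /
#'     0.004).}
#'   \item{death_delay_mean}{mean months from recurrence to death
#'     (exponential); default 12.}
#'   \item{censor_horizon}{administrative censoring in months from
#'     surgery; default 48.}
#'   \item{artifact_rate}{mean one-off low-level artifact rows injected
#'     per cfDNA sample; default 1.}
#'   \item{age_min, age_max}{uniform patient age range; defaults 40, 80.}
#'   \item{postop_sample_month}{month of the postoperative blood draw
#'     relative to surgery; default 1.5 (~6.5 weeks).}
#'   \item{seed}{RNG seed for [simulate_cohort()].}
#' }
#'
#' @param n_patients number of patients.
#' @param ... overrides of the fields above.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients, ...) {
  cfg <- list(n_patients = as.integer(n_patients),
              coverage_mean = 30000,
              wbc_coverage_mean = NULL,
              ch_burden_age0 = 0.05,
              ch_rate_per_year = 0.05,
              ch_maf_log_mean = log(0.003),
              ch_maf_log_sd = 0.9,
              tumor_maf_log_mean = log(0.003),
              tumor_maf_log_sd = 0.8,
              tumor_maf_min = 0.001,
              tumor_variants_mean = 2,
              shed_prob_intestinal = 0.75,
              shed_prob_diffuse = 0.40,
              shed_prob_other = 0.50,
              p_responder = 0.3,
              clearance_prob_responder = 0.9,
              clearance_prob_nonresponder = 0.15,
              mrd_prob_persistent = 0.6,
              frag_len_tumor_mean = 145,
              frag_len_wt_mean = 167,
              frag_len_sd = 25,
              hazard_mrd_pos = 0.08,
              hazard_mrd_neg = 0.004,
              death_delay_mean = 12,
              censor_horizon = 48,
              artifact_rate = 1,
              age_min = 40,
              age_max = 80,
              postop_sample_month = 1.5,
              seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0)
    config_stop(paste0("unknown simulation key(s): ",
                       paste(unknown, collapse = ", ")))
  cfg[names(override)] <- override
  probs <- c("shed_prob_intestinal", "shed_prob_diffuse", "shed_prob_other",
             "p_responder", "clearance_prob_responder",
             "clearance_prob_nonresponder", "mrd_prob_persistent")
  for (key in probs)
    if (cfg[[key]] < 0 || cfg[[key]] > 1)
      config_stop(paste0(key, " must lie in [0, 1]"))
  for (key in c("coverage_mean", "frag_len_tumor_mean", "frag_len_wt_mean",
                "frag_len_sd", "hazard_mrd_pos", "hazard_mrd_neg",
                "censor_horizon"))
    if (cfg[[key]] <= 0) config_stop(paste0(key, " must be positive"))
  if (cfg$hazard_mrd_pos <= cfg$hazard_mrd_neg)
    config_stop("hazard_mrd_pos must exceed hazard_mrd_neg")
  structure(cfg, class = "simulation_config")
}

#' Draw a patient's clonal-hematopoiesis variant burden
#'
#' The number of CH variants is Poisson with mean
#' `ch_burden_age0 * exp(ch_rate_per_year * age)`, i.e. an expected burden
#' that grows exponentially with age, mirroring the observed age
#' dependence of WBC variant counts. Uses R's global RNG; seed the session
#' for reproducibility.
#'
#' @param age_years patient age(s), non-negative.
#' @param config a `simulation_config`.
#' @return integer vector of variant counts, one per age.
#' @export
sample_ch_burden <- function(age_years, config) {
  if (any(age_years < 0)) validation_stop("negative age")
  mu <- config$ch_burden_age0 * exp(config$ch_rate_per_year * age_years)
  stats::rpois(length(age_years), mu)
}

#' Draw distinct-read-pair counts at one locus
#'
#' Coverage is Poisson around `coverage_mean` truncated at 1 (a covered
#' panel position always yields at least one distinct pair); the altered
#' count is binomial in the coverage with success probability `theta`,
#' the sampling model the origin classifier assumes.
#'
#' @param theta allele fraction(s) in \[0, 1\].
#' @param coverage_mean mean distinct coverage.
#' @return data.frame with columns `k_alt`, `n_distinct`, one row per
#'   theta.
#' @export
sample_read_counts <- function(theta, coverage_mean) {
  if (any(theta < 0 | theta > 1))
    validation_stop("theta outside [0, 1]")
  m <- length(theta)
  n <- stats::rpois(m, coverage_mean)
  while (any(n < 1)) {
    idx <- which(n < 1)
    n[idx] <- stats::rpois(length(idx), coverage_mean)
  }
  k <- stats::rbinom(m, n, theta)
  data.frame(k_alt = k, n_distinct = n)
}

#' Draw cfDNA fragment lengths for one origin class
#'
#' Normal lengths rounded to integer bp and truncated above 0, with mean
#' `frag_len_tumor_mean` for tumor-derived fragments and
#' `frag_len_wt_mean` for hematopoietic and wild-type fragments.
#'
#' @param origin one of `"tumor"`, `"hematopoietic"`, `"wildtype"`.
#' @param n_frags number of fragments (>= 0).
#' @param config a `simulation_config`.
#' @return integer vector of lengths in bp.
#' @export
simulate_fragments <- function(origin, n_frags, config) {
  origin <- match.arg(origin, c("tumor", "hematopoietic", "wildtype"))
  if (n_frags < 0) validation_stop("n_frags must be >= 0")
  if (n_frags == 0) return(integer(0))
  mu <- if (origin == "tumor") config$frag_len_tumor_mean else
    config$frag_len_wt_mean
  len <- round(stats::rnorm(n_frags, mu, config$frag_len_sd))
  while (any(len < 1))
    len[len < 1] <- round(stats::rnorm(sum(len < 1), mu, config$frag_len_sd))
  as.integer(len)
}

#' Simulate a labeled fragment-length table
#'
#' Convenience wrapper building the `FragmentRecord` table consumed by
#' [compare_fragment_classes()], with `n_per_class` fragments in each of
#' the tumor, hematopoietic and wild-type classes.
#'
#' @param config a `simulation_config`.
#' @param n_per_class fragments per origin class.
#' @return data.frame with columns `patient_id`, `variant_key`,
#'   `origin_class`, `length_bp`.
#' @export
simulate_fragment_table <- function(config, n_per_class = 300) {
  classes <- c("tumor", "hematopoietic", "wildtype")
  do.call(rbind, lapply(classes, function(cl) {
    data.frame(patient_id = "pooled",
               variant_key = if (cl == "wildtype") "wild-type" else
                 paste0("chr17:7578000:C:T"),
               origin_class = cl,
               length_bp = simulate_fragments(cl, n_per_class, config),
               stringsAsFactors = FALSE)
  }))
}

# draw a variant locus from a weighted panel, rejecting keys already used
# for this patient so every row maps to exactly one truth label
draw_locus <- function(panel, used_keys) {
  repeat {
    i <- sample.int(nrow(panel), 1, prob = panel$weight)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    loc <- data.frame(gene = panel$gene[i], chrom = panel$chrom[i],
                      pos = panel$base[i] + sample.int(20000, 1),
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
    if (!variant_key(loc) %in% used_keys) return(loc)
  }
}

#' Simulate a matched cfDNA/WBC cohort with ground truth
#'
#' Generates, per patient: a Lauren subtype, an age-dependent CH variant
#' burden observed in both compartments at the same underlying allele
#' fraction at every timepoint, tumor-only cfDNA variants gated by a
#' subtype-specific shedding probability, therapy-induced clearance tied
#' to pathologic response (TRG), surgery-driven postoperative MRD status,
#' and exponential recurrence/survival outcomes keyed to that MRD status
#' with administrative censoring. An observation row is emitted whenever
#' the underlying allele fraction at that sample is positive (so a 0-read
#' draw at real signal still yields a row), and never otherwise; WBC is
#' sequenced once, at baseline, matching the study design.
#'
#' @param config a `simulation_config`.
#' @return list with elements `observations` (variant observation table),
#'   `clinical` (clinical table with `ypn_positive` logical), and `truth`
#'   (list of `variants` origin labels and `patients` per-timepoint MRD
#'   status plus true recurrence time).
#' @export
simulate_cohort <- function(config) {
  if (config$n_patients < 0) validation_stop("n_patients must be >= 0")
  set.seed(config$seed)
  obs_list <- list()
  truth_var_list <- list()
  clin_list <- list()
  truth_pat_list <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    age <- round(stats::runif(1, config$age_min, config$age_max))
    subtype <- sample(c("intestinal", "diffuse", "other"), 1,
                      prob = c(0.48, 0.48, 0.04))
    arm <- sample(arm_levels, 1)
    responder <- stats::runif(1) < config$p_responder
    trg <- if (responder) sample(1:2, 1, prob = c(0.45, 0.55)) else
      sample(3:5, 1, prob = c(0.3, 0.3, 0.4))
    ypn <- stats::runif(1) < if (responder) 0.2 else 0.6

    shed_p <- switch(subtype,
                     intestinal = config$shed_prob_intestinal,
                     diffuse = config$shed_prob_diffuse,
                     config$shed_prob_other)
    shedder <- stats::runif(1) < shed_p
    clear_p <- if (responder) config$clearance_prob_responder else
      config$clearance_prob_nonresponder
    cleared <- shedder && stats::runif(1) < clear_p
    mrd_postop <- shedder && !cleared &&
      stats::runif(1) < config$mrd_prob_persistent

    variants <- list()
    used_keys <- character(0)
    n_ch <- sample_ch_burden(age, config)
    for (v in seq_len(n_ch)) {
      loc <- draw_locus(ch_panel, used_keys)
      used_keys <- c(used_keys, variant_key(loc))
      theta <- stats::rlnorm(1, config$ch_maf_log_mean, config$ch_maf_log_sd)
      variants[[length(variants) + 1]] <- list(
        loc = loc, origin = "hematopoietic",
        theta = c(baseline = theta, preoperative = theta,
                  postoperative = theta),
        wbc_theta = theta,
        consequence = sample(callable_consequences, 1,
                             prob = c(0.7, 0.1, 0.1, 0.1)))
    }
    if (shedder) {
      n_tv <- max(1L, stats::rpois(1, config$tumor_variants_mean))
      for (v in seq_len(n_tv)) {
        loc <- draw_locus(tumor_panel, used_keys)
        used_keys <- c(used_keys, variant_key(loc))
        theta <- stats::rlnorm(1, config$tumor_maf_log_mean,
                               config$tumor_maf_log_sd)
        while (theta < config$tumor_maf_min)
          theta <- stats::rlnorm(1, config$tumor_maf_log_mean,
                                 config$tumor_maf_log_sd)
        th <- c(baseline = theta,
                preoperative = if (cleared) 0 else theta,
                postoperative = if (mrd_postop) theta else 0)
        variants[[length(variants) + 1]] <- list(
          loc = loc, origin = "tumor", theta = th, wbc_theta = 0,
          consequence = sample(callable_consequences, 1,
                               prob = c(0.75, 0.1, 0.1, 0.05)))
      }
    }
    # one-off low-level artifacts, single timepoint only
    for (tp in tp_levels) {
      n_art <- stats::rpois(1, config$artifact_rate)
      for (v in seq_len(n_art)) {
        loc <- draw_locus(tumor_panel, used_keys)
        used_keys <- c(used_keys, variant_key(loc))
        th <- c(baseline = 0, preoperative = 0, postoperative = 0)
        th[tp] <- 3e-5
        variants[[length(variants) + 1]] <- list(
          loc = loc, origin = "artifact", theta = th, wbc_theta = 0,
          consequence = sample(consequence_levels, 1))
      }
    }

    for (v in variants) {
      truth_var_list[[length(truth_var_list) + 1]] <- cbind(
        data.frame(patient_id = pid, stringsAsFactors = FALSE),
        v$loc, data.frame(origin = v$origin, stringsAsFactors = FALSE))
      aa <- paste0("p.X", v$loc$pos %% 1000)
      wbc_cov <- if (is.null(config$wbc_coverage_mean))
        config$coverage_mean else config$wbc_coverage_mean
      emit <- function(tp, compartment, theta) {
        cov_mean <- if (compartment == "WBC") wbc_cov else
          config$coverage_mean
        counts <- sample_read_counts(theta, cov_mean)
        data.frame(patient_id = pid,
                   sample_id = paste(pid, tp, compartment, sep = "_"),
                   timepoint = tp, compartment = compartment,
                   gene = v$loc$gene, chrom = v$loc$chrom, pos = v$loc$pos,
                   ref = v$loc$ref, alt = v$loc$alt,
                   consequence = v$consequence, aa_change = aa,
                   n_distinct = counts$n_distinct, k_alt = counts$k_alt,
                   stringsAsFactors = FALSE)
      }
      for (tp in tp_levels)
        if (v$theta[[tp]] > 0)
          obs_list[[length(obs_list) + 1]] <- emit(tp, "cfDNA", v$theta[[tp]])
      if (v$wbc_theta > 0)
        obs_list[[length(obs_list) + 1]] <-
          emit("baseline", "WBC", v$wbc_theta)
    }

    # outcomes, months from surgery
    haz <- if (mrd_postop) config$hazard_mrd_pos else config$hazard_mrd_neg
    t_rec <- stats::rexp(1, haz)
    horizon <- config$censor_horizon
    recurred <- t_rec < horizon
    t_death <- t_rec + stats::rexp(1, 1 / config$death_delay_mean)
    died <- recurred && t_death < horizon
    clin_list[[i]] <- data.frame(
      patient_id = pid, age_years = age, lauren_subtype = subtype,
      trg = trg, ypn_positive = ypn, arm = arm,
      efs_months = if (recurred) t_rec else horizon,
      efs_event = recurred,
      os_months = if (died) t_death else horizon,
      os_event = died,
      recurrence_months = if (recurred) t_rec else NA_real_,
      postop_sample_months = config$postop_sample_month,
      stringsAsFactors = FALSE)
    truth_pat_list[[i]] <- data.frame(
      patient_id = pid, shedder = shedder, responder = responder,
      cleared_preop = cleared,
      mrd_baseline = shedder, mrd_preoperative = shedder && !cleared,
      mrd_postoperative = mrd_postop,
      true_recurrence_months = t_rec, stringsAsFactors = FALSE)
  }

  empty_obs <- data.frame(matrix(ncol = length(obs_columns), nrow = 0,
                                 dimnames = list(NULL, obs_columns)))
  observations <- if (length(obs_list) > 0)
    do.call(rbind, obs_list) else empty_obs
  rownames(observations) <- NULL
  if (nrow(observations) > 0)
    observations$maf <- maf_fraction(observations$k_alt,
                                     observations$n_distinct)
  clinical <- if (length(clin_list) > 0) do.call(rbind, clin_list) else
    data.frame()
  truth_variants <- if (length(truth_var_list) > 0)
    do.call(rbind, truth_var_list) else data.frame()
  truth_patients <- if (length(truth_pat_list) > 0)
    do.call(rbind, truth_pat_list) else data.frame()
  rownames(clinical) <- rownames(truth_variants) <-
    rownames(truth_patients) <- NULL
  list(observations = observations, clinical = clinical,
       truth = list(variants = truth_variants, patients = truth_patients))
}

#' Write a simulated cohort to a directory of TSVs
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_variant_observations(cohort$observations,
                             file.path(dir, "observations.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(cohort$truth$variants,
                     file.path(dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$patients,
                     file.path(dir, "truth_patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
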