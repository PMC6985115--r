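# Data model, readers/writers and configuration for the MRD pipeline.
#
# All tables are plain tab-separated text with a header row; records are
# held as base data.frames so every downstream stage can be audited with
# ordinary R tooling.

#' @keywords internal
"_PACKAGE"

## ---- controlled vocabularies -------------------------------------------

#' Controlled vocabularies of the data model
#'
#' Timepoints follow the perioperative study design (one blood draw at
#' enrollment, one after preoperative chemotherapy, one after surgery);
#' compartments distinguish plasma cell-free DNA from the white-blood-cell
#' genomic DNA control.
#'
#' @name vocabularies
#' @keywords internal
NULL

tp_levels <- c("baseline", "preoperative", "postoperative")
compartment_levels <- c("cfDNA", "WBC")
consequence_levels <- c("missense", "nonsense", "frameshift", "splice",
                        "inframe_indel", "synonymous", "noncoding")
subtype_levels <- c("intestinal", "diffuse", "other")
arm_levels <- c("chemotherapy", "chemoradiotherapy")

obs_columns <- c("patient_id", "sample_id", "timepoint", "compartment",
                 "gene", "chrom", "pos", "ref", "alt", "consequence",
                 "aa_change", "n_distinct", "k_alt")

clinical_columns <- c("patient_id", "age_years", "lauren_subtype", "trg",
                      "ypn", "arm", "efs_months", "efs_event", "os_months",
                      "os_event", "recurrence_months", "postop_sample_months")

## ---- typed error helpers ------------------------------------------------

ctdna_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ctdnamrd_error")))
}

schema_stop <- function(msg) ctdna_stop(msg, "ctdnamrd_schema_error")
validation_stop <- function(msg) ctdna_stop(msg, "ctdnamrd_validation_error")
config_stop <- function(msg) ctdna_stop(msg, "ctdnamrd_config_error")

#' Variant key string for joining one variant across samples
#'
#' The (chrom, pos, ref, alt) tuple identifies a variant across all samples
#' of a patient; indel alleles are explicit left-anchored strings, never
#' hyphen notation.
#'
#' @param df data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys, one per row.
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

## ---- variant observations ----------------------------------------------

#' Validate a variant observation table
#'
#' Checks the schema and per-row invariants of the observation model:
#' `k_alt <= n_distinct`, `pos >= 1`, counts non-negative, and the
#' timepoint/compartment/consequence vocabularies. Failures name the
#' offending column or row so malformed input is never silently loaded.
#'
#' @param df data.frame to validate.
#' @return `df`, invisibly, if valid.
#' @export
validate_variant_observations <- function(df) {
  missing_cols <- setdiff(obs_columns, names(df))
  if (length(missing_cols) > 0)
    schema_stop(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0) return(invisible(df))
  chk <- function(bad, what) {
    if (any(bad))
      validation_stop(sprintf("%s in row(s) %s", what,
                              paste(which(bad), collapse = ", ")))
  }
  chk(!df$timepoint %in% tp_levels, "unknown timepoint label")
  chk(!df$compartment %in% compartment_levels, "unknown compartment label")
  chk(!df$consequence %in% consequence_levels, "unknown consequence label")
  chk(is.na(df$pos) | df$pos < 1, "pos must be >= 1")
  chk(is.na(df$n_distinct) | df$n_distinct < 0, "negative n_distinct")
  chk(is.na(df$k_alt) | df$k_alt < 0, "negative k_alt")
  chk(df$k_alt > df$n_distinct, "k_alt exceeds n_distinct")
  invisible(df)
}

#' Read a variant observation table
#'
#' One row per locus per sample, with distinct-read-pair evidence: the
#' total distinct coverage `n_distinct` and the altered distinct pairs
#' `k_alt` whose ratio is the mutant allele fraction (MAF). Input order is
#' preserved; any invariant violation aborts the load with a row-level
#' diagnostic.
#'
#' @param path path to a TSV with the columns
#'   `patient_id sample_id timepoint compartment gene chrom pos ref alt
#'   consequence aa_change n_distinct k_alt`.
#' @return data.frame of validated observations with an added `maf`
#'   fraction column (`k_alt / n_distinct`, 0 where coverage is 0).
#' @export
read_variant_observations <- function(path) {
  if (!file.exists(path)) schema_stop(paste0("no such file: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(obs_columns, names(df))
  if (length(missing_cols) > 0)
    schema_stop(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  df <- df[, obs_columns]
  for (col in c("pos", "n_distinct", "k_alt")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (nrow(df) > 0 && anyNA(v))
      validation_stop(sprintf("non-integer %s in row(s) %s", col,
                              paste(which(is.na(v)), collapse = ", ")))
    df[[col]] <- v
  }
  validate_variant_observations(df)
  df$maf <- maf_fraction(df$k_alt, df$n_distinct)
  df
}

#' Write a variant observation table
#'
#' Inverse of [read_variant_observations()]; a write/read round trip
#' reproduces the records field for field.
#'
#' @param df observation data.frame.
#' @param path output TSV path.
#' @export
write_variant_observations <- function(df, path) {
  validate_variant_observations(df)
  utils::write.table(df[, obs_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mutant allele fraction from distinct-read counts
#'
#' @param k_alt altered distinct read pairs.
#' @param n_distinct total distinct read pairs (0 coverage yields MAF 0).
#' @return fraction in \[0, 1\]. Multiply by 100 for the percent scale used
#'   in reports.
#' @export
maf_fraction <- function(k_alt, n_distinct) {
  ifelse(n_distinct > 0, k_alt / n_distinct, 0)
}

## ---- clinical records ---------------------------------------------------

parse_logical <- function(x) {
  out <- rep(NA, length(x))
  x <- tolower(trimws(as.character(x)))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

parse_num <- function(x) suppressWarnings(as.numeric(ifelse(trimws(x) == "",
                                                            NA, x)))

#' Read the clinical covariate and outcome table
#'
#' Enum fields (Lauren subtype, treatment arm, ypN status) are normalized
#' case-insensitively; missing values stay missing and are never imputed.
#' The Mandard tumor regression grade (TRG) runs 1 (complete regression)
#' to 5 (no regression) and is missing for unresected patients.
#'
#' @param path TSV with columns `patient_id age_years lauren_subtype trg
#'   ypn arm efs_months efs_event os_months os_event recurrence_months
#'   postop_sample_months`. `ypn` accepts `ypN0`/`ypN+` (any case) or
#'   empty.
#' @return data.frame with `ypn` parsed to a logical `ypn_positive`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) schema_stop(paste0("no such file: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(clinical_columns, names(df))
  if (length(missing_cols) > 0)
    schema_stop(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  out <- data.frame(patient_id = df$patient_id,
                    age_years = parse_num(df$age_years),
                    lauren_subtype = tolower(trimws(df$lauren_subtype)),
                    trg = suppressWarnings(as.integer(
                      ifelse(trimws(df$trg) == "", NA, df$trg))),
                    stringsAsFactors = FALSE)
  ypn <- tolower(trimws(df$ypn))
  out$ypn_positive <- rep(NA, nrow(df))
  out$ypn_positive[ypn %in% c("ypn0", "n0", "negative", "false", "0")] <- FALSE
  out$ypn_positive[grepl("^ypn[1-3+]", ypn) |
                     ypn %in% c("positive", "true", "1")] <- TRUE
  out$arm <- tolower(trimws(df$arm))
  out$efs_months <- parse_num(df$efs_months)
  out$efs_event <- parse_logical(df$efs_event)
  out$os_months <- parse_num(df$os_months)
  out$os_event <- parse_logical(df$os_event)
  out$recurrence_months <- parse_num(df$recurrence_months)
  out$postop_sample_months <- parse_num(df$postop_sample_months)

  bad_sub <- !(out$lauren_subtype %in% subtype_levels | out$lauren_subtype == "")
  if (any(bad_sub))
    validation_stop(sprintf("unknown lauren_subtype in row(s) %s",
                            paste(which(bad_sub), collapse = ", ")))
  out$lauren_subtype[out$lauren_subtype == ""] <- NA
  bad_arm <- !(out$arm %in% arm_levels | out$arm == "")
  if (any(bad_arm))
    validation_stop(sprintf("unknown arm in row(s) %s",
                            paste(which(bad_arm), collapse = ", ")))
  out$arm[out$arm == ""] <- NA
  bad_trg <- !is.na(out$trg) & (out$trg < 1 | out$trg > 5)
  if (any(bad_trg))
    validation_stop(sprintf("trg outside 1-5 in row(s) %s",
                            paste(which(bad_trg), collapse = ", ")))
  bad_surv <- !is.na(out$efs_months) & !is.na(out$os_months) &
    out$efs_event %in% TRUE & out$os_event %in% TRUE &
    out$efs_months > out$os_months
  if (any(bad_surv))
    validation_stop(sprintf(
      "efs_months exceeds os_months with both events observed in row(s) %s",
      paste(which(bad_surv), collapse = ", ")))
  out
}

#' Write a clinical table readable by [read_clinical_table()]
#'
#' @param df clinical data.frame as produced by [read_clinical_table()] or
#'   [simulate_cohort()] (logical `ypn_positive` is rendered as
#'   `ypN0`/`ypN+`).
#' @param path output TSV path.
#' @export
write_clinical_table <- function(df, path) {
  out <- data.frame(patient_id = df$patient_id,
                    age_years = df$age_years,
                    lauren_subtype = df$lauren_subtype,
                    trg = df$trg,
                    ypn = ifelse(is.na(df$ypn_positive), "",
                                 ifelse(df$ypn_positive, "ypN+", "ypN0")),
                    arm = df$arm,
                    efs_months = df$efs_months,
                    efs_event = df$efs_event,
                    os_months = df$os_months,
                    os_event = df$os_event,
                    recurrence_months = df$recurrence_months,
                    postop_sample_months = df$postop_sample_months,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

## ---- catalogs -----------------------------------------------------------

#' Read a hotspot catalog (COSMIC-style)
#'
#' A variant is a somatic hotspot when its nucleotide change and amino acid
#' change match a catalog entry recorded in at least `hotspot_min_count`
#' (default 20) cancer cases.
#'
#' @param path TSV with columns `chrom pos ref alt aa_change cosmic_count`.
#' @return data.frame of hotspot entries.
#' @export
read_hotspot_catalog <- function(path) {
  if (!file.exists(path)) schema_stop(paste0("no such file: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "aa_change", "cosmic_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    schema_stop(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  if (any(df$cosmic_count < 0))
    validation_stop("negative cosmic_count")
  df
}

#' Read a germline variant catalog (dbSNP-style)
#'
#' @param path TSV with columns `chrom pos ref alt`.
#' @return data.frame of germline entries (unique keys).
#' @export
read_germline_catalog <- function(path) {
  if (!file.exists(path)) schema_stop(paste0("no such file: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    schema_stop(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  unique(df[, need])
}

## ---- pipeline configuration --------------------------------------------

#' Pipeline configuration
#'
#' All tunable thresholds of the calling and origin model in one immutable
#' object:
#' \describe{
#'   \item{maf_threshold}{minimum MAF (fraction) for the read-support rule;
#'     default 5e-4, i.e. 0.05\% of total distinct read pairs.}
#'   \item{min_distinct_reads}{minimum altered distinct pairs for the
#'     read-support rule; default 3.}
#'   \item{rescue_min_reads}{minimum altered pairs for the cross-timepoint
#'     rescue rule; default 1.}
#'   \item{wbc_filter_min_reads}{altered WBC pairs at which a cfDNA call is
#'     classed hematopoietic; default 1 (a single distinct read).}
#'   \item{hotspot_min_count}{COSMIC case count defining a hotspot;
#'     default 20.}
#'   \item{prior_alpha, prior_beta}{Beta prior shapes on the cfDNA allele
#'     fraction under the origin model; defaults 2.4 and 340 (prior mean
#'     ~0.7\%, equivalent to 2.4 altered reads per 340 molecules).}
#'   \item{mc_draws}{Monte Carlo prior draws for the sampling estimator of
#'     the marginal likelihood; default 1e5.}
#'   \item{accept_inframe_indel}{whether in-frame indels pass the
#'     consequence rule alongside missense/nonsense/frameshift/splice;
#'     default TRUE.}
#'   \item{p_min}{optional minimum posterior tumor-origin probability
#'     additionally required for detection; default 0 (off).}
#'   \item{blacklist}{optional data.frame of loci (chrom,pos,ref,alt) to
#'     drop as alignment artifacts; default empty.}
#'   \item{rng_seed}{seed for the Monte Carlo estimator.}
#' }
#'
#' @param ... overrides of the fields above.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(maf_threshold = 5e-4,
              min_distinct_reads = 3L,
              rescue_min_reads = 1L,
              wbc_filter_min_reads = 1L,
              hotspot_min_count = 20L,
              prior_alpha = 2.4,
              prior_beta = 340,
              mc_draws = 100000L,
              accept_inframe_indel = TRUE,
              p_min = 0,
              blacklist = NULL,
              rng_seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0)
    config_stop(paste0("unknown config key(s): ",
                       paste(unknown, collapse = ", ")))
  cfg[names(override)] <- override
  for (key in c("maf_threshold", "min_distinct_reads", "rescue_min_reads",
                "wbc_filter_min_reads", "hotspot_min_count", "prior_alpha",
                "prior_beta")) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 ||
        is.na(cfg[[key]]) || cfg[[key]] <= 0)
      config_stop(paste0(key, " must be a positive number"))
  }
  if (cfg$mc_draws < 100)
    config_stop("mc_draws below 100: Monte Carlo estimator unusable")
  if (cfg$p_min < 0 || cfg$p_min > 1)
    config_stop("p_min must lie in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat key/value YAML; keys absent from the file take the package
#' defaults, unknown keys raise an error (no silent typo tolerance).
#'
#' @param path YAML file; `NULL` returns the all-defaults configuration.
#' @return `pipeline_config` object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  if (!file.exists(path)) config_stop(paste0("no such file: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("MRD pipeline configuration\n")
  for (key in setdiff(names(x), "blacklist"))
    cat(sprintf("  %-22s %s\n", key, format(x[[key]])))
  cat(sprintf("  %-22s %d loci\n", "blacklist",
              if (is.null(x$blacklist)) 0L else nrow(x$blacklist)))
  invisible(x)
}
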