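# Rule-based candidate somatic mutation calling on distinct-read-pair
# counts, applied independently per compartment.
#
# A variant observation becomes a candidate call when it satisfies, in one
# sample: read support (R1: >= 3 distinct altered pairs AND MAF >= 0.05%,
# both inclusive) or cross-timepoint rescue (R2: >= 1 altered pair here
# while the identical variant passes R1 at another timepoint of the same
# patient and compartment); absence from the germline catalog (R4); and a
# protein-altering consequence (R6). Loci on a user-supplied blacklist
# (alignment artifacts / paralogs, R5) are rejected up front. Hotspot
# status is an annotation, not a calling rule.

rule_ids <- c("R1_reads_maf", "R2_rescue", "R4_germline", "R6_consequence")

#' Read-support rule (R1)
#'
#' TRUE where the altered distinct-pair count reaches
#' `min_distinct_reads` and the MAF reaches `maf_threshold`, both
#' inclusive. Zero-coverage rows fail (degenerate coverage).
#'
#' @param obs observation data.frame (vectorized over rows).
#' @param config a [pipeline_config()].
#' @return logical vector.
#' @export
apply_read_support_rule <- function(obs, config = pipeline_config()) {
  obs$n_distinct > 0 &
    obs$k_alt >= config$min_distinct_reads &
    maf_fraction(obs$k_alt, obs$n_distinct) >= config$maf_threshold
}

#' Cross-timepoint rescue rule (R2)
#'
#' A low-level observation (>= `rescue_min_reads` altered pairs) is
#' rescued when the identical variant key passes the read-support rule at
#' at least one other timepoint of the same patient and compartment, past
#' or future.
#'
#' @param obs single-row observation data.frame.
#' @param other_timepoints observations of the same patient and
#'   compartment at timepoints other than `obs`'s own.
#' @param config a [pipeline_config()].
#' @return logical scalar.
#' @export
apply_rescue_rule <- function(obs, other_timepoints,
                              config = pipeline_config()) {
  if (nrow(obs) != 1) validation_stop("obs must be a single row")
  if (obs$k_alt < config$rescue_min_reads) return(FALSE)
  if (nrow(other_timepoints) == 0) return(FALSE)
  if (any(other_timepoints$timepoint == obs$timepoint))
    validation_stop("other_timepoints must exclude obs's own timepoint")
  same <- other_timepoints[variant_key(other_timepoints) == variant_key(obs), ,
                           drop = FALSE]
  nrow(same) > 0 && any(apply_read_support_rule(same, config))
}

#' Germline (R4) and consequence (R6) annotation rules
#'
#' R4 passes when the variant key is absent from the germline catalog.
#' R6 passes for missense, nonsense, frameshift and splice alterations;
#' in-frame indels also pass by default (`accept_inframe_indel`) since
#' they are protein-altering coding changes, while synonymous and
#' noncoding changes fail.
#'
#' @param obs observation data.frame (vectorized over rows).
#' @param germline_catalog data.frame with `chrom pos ref alt`.
#' @param config a [pipeline_config()].
#' @return list with logical vectors `germline_pass`, `consequence_pass`.
#' @export
apply_annotation_rules <- function(obs, germline_catalog,
                                   config = pipeline_config()) {
  gl_keys <- if (is.null(germline_catalog) || nrow(germline_catalog) == 0)
    character(0) else variant_key(germline_catalog)
  accepted <- c("missense", "nonsense", "frameshift", "splice")
  if (isTRUE(config$accept_inframe_indel))
    accepted <- c(accepted, "inframe_indel")
  list(germline_pass = !variant_key(obs) %in% gl_keys,
       consequence_pass = obs$consequence %in% accepted)
}

#' Call candidate somatic mutations for one patient and compartment
#'
#' Applies R1/R2/R4/R6 (and the optional locus blacklist) to every input
#' row; every row appears exactly once in the output with its call status
#' and, for rejections, the first failing rule in the order consequence,
#' germline, blacklist, read support.
#'
#' @param obs observations sharing one `patient_id` and one `compartment`.
#' @param germline_catalog data.frame with `chrom pos ref alt` (may be
#'   empty).
#' @param config a [pipeline_config()].
#' @return the input rows plus `maf_percent`, `passed_rules` (comma-joined
#'   rule ids), `call_status` (`called`/`rejected`), `rejection_reason`.
#' @export
call_candidates <- function(obs, germline_catalog = NULL,
                            config = pipeline_config()) {
  validate_variant_observations(obs)
  if (nrow(obs) == 0) {
    out <- obs
    out$maf_percent <- numeric(0)
    out$passed_rules <- character(0)
    out$call_status <- character(0)
    out$rejection_reason <- character(0)
    return(out)
  }
  if (length(unique(obs$patient_id)) > 1)
    validation_stop("mixed patients in call_candidates input")
  if (length(unique(obs$compartment)) > 1)
    validation_stop("mixed compartments in call_candidates input")

  r1 <- apply_read_support_rule(obs, config)
  keys <- variant_key(obs)
  # a key is rescuable at timepoint t when it passes R1 at some other
  # timepoint; precompute R1-passing timepoints per key
  r2 <- vapply(seq_len(nrow(obs)), function(i) {
    if (obs$k_alt[i] < config$rescue_min_reads) return(FALSE)
    other <- keys == keys[i] & obs$timepoint != obs$timepoint[i]
    any(r1[other])
  }, logical(1))
  ann <- apply_annotation_rules(obs, germline_catalog, config)
  bl <- config$blacklist
  blacklisted <- if (is.null(bl) || nrow(bl) == 0) rep(FALSE, nrow(obs)) else
    keys %in% variant_key(bl)

  called <- (r1 | r2) & ann$germline_pass & ann$consequence_pass &
    !blacklisted
  reason <- ifelse(called, "",
            ifelse(!ann$consequence_pass, "R6_consequence",
            ifelse(!ann$germline_pass, "R4_germline",
            ifelse(blacklisted, "R5_blacklist", "R1_reads_maf"))))
  passed <- vapply(seq_len(nrow(obs)), function(i) {
    paste(rule_ids[c(r1[i], r2[i], ann$germline_pass[i],
                     ann$consequence_pass[i])], collapse = ",")
  }, character(1))

  out <- obs
  out$maf_percent <- 100 * maf_fraction(obs$k_alt, obs$n_distinct)
  out$passed_rules <- passed
  out$call_status <- ifelse(called, "called", "rejected")
  out$rejection_reason <- reason
  out
}

#' Annotate hotspot status against a COSMIC-style catalog
#'
#' A call is a somatic hotspot when its nucleotide change
#' (chrom, pos, ref, alt) and its amino acid change both match a catalog
#' entry reported in at least `hotspot_min_count` cancer cases.
#'
#' @param calls output of [call_candidates()].
#' @param hotspot_catalog data.frame with
#'   `chrom pos ref alt aa_change cosmic_count`.
#' @param config a [pipeline_config()].
#' @return `calls` with a logical `is_hotspot` column.
#' @export
annotate_hotspots <- function(calls, hotspot_catalog,
                              config = pipeline_config()) {
  if (nrow(calls) == 0) {
    calls$is_hotspot <- logical(0)
    return(calls)
  }
  hs <- hotspot_catalog[hotspot_catalog$cosmic_count >=
                          config$hotspot_min_count, , drop = FALSE]
  hs_id <- paste(variant_key(hs), hs$aa_change, sep = "|")
  calls$is_hotspot <- paste(variant_key(calls), calls$aa_change,
                            sep = "|") %in% hs_id
  calls
}

#' Call candidates across a whole cohort
#'
#' Convenience loop over every (patient, compartment) stratum of an
#' observation table; calling is independent per compartment.
#'
#' @param observations observation table (any number of patients).
#' @param germline_catalog optional germline catalog.
#' @param hotspot_catalog optional hotspot catalog (adds `is_hotspot`).
#' @param config a [pipeline_config()].
#' @return row-bound calls table.
#' @export
call_cohort <- function(observations, germline_catalog = NULL,
                        hotspot_catalog = NULL,
                        config = pipeline_config()) {
  strata <- unique(observations[, c("patient_id", "compartment")])
  pieces <- lapply(seq_len(nrow(strata)), function(i) {
    sub <- observations[observations$patient_id == strata$patient_id[i] &
                          observations$compartment == strata$compartment[i], ,
                        drop = FALSE]
    call_candidates(sub, germline_catalog, config)
  })
  out <- if (length(pieces) > 0) do.call(rbind, pieces) else
    call_candidates(observations[0, , drop = FALSE], germline_catalog,
                    config)
  rownames(out) <- NULL
  if (!is.null(hotspot_catalog))
    out <- annotate_hotspots(out, hotspot_catalog, config)
  out
}
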