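cfg <- pipeline_config()

test_that("read-support rule holds at its inclusive boundaries", {
  # exactly 3 reads at exactly 0.05% MAF passes (both thresholds inclusive)
  expect_true(apply_read_support_rule(make_obs(k_alt = 3, n_distinct = 6000),
                                      cfg))
  # MAF below threshold fails despite 3 reads
  expect_false(apply_read_support_rule(make_obs(k_alt = 3,
                                                n_distinct = 10000), cfg))
  # reads below 3 fail despite high MAF
  expect_false(apply_read_support_rule(make_obs(k_alt = 2, n_distinct = 1000),
                                       cfg))
  # degenerate zero coverage fails
  expect_false(apply_read_support_rule(make_obs(k_alt = 0, n_distinct = 0),
                                       cfg))
})

test_that("rescue requires a qualifying sibling timepoint", {
  here <- make_obs(timepoint = "preoperative", k_alt = 1)
  good_sib <- make_obs(timepoint = "baseline", k_alt = 4, n_distinct = 7000)
  weak_sib <- make_obs(timepoint = "baseline", k_alt = 2, n_distinct = 7000)
  expect_true(apply_rescue_rule(here, good_sib, cfg))
  expect_false(apply_rescue_rule(here, weak_sib, cfg))
  zero <- here
  zero$k_alt <- 0L
  expect_false(apply_rescue_rule(zero, good_sib, cfg))
  # sibling at a different locus cannot rescue
  other_locus <- good_sib
  other_locus$pos <- other_locus$pos + 1L
  expect_false(apply_rescue_rule(here, other_locus, cfg))
  expect_error(apply_rescue_rule(here, here, cfg),
               class = "ctdnamrd_validation_error")
})

test_that("germline and consequence rules follow the catalogs", {
  obs <- rbind(make_obs(),
               make_obs(pos = 7577200L, consequence = "synonymous"),
               make_obs(pos = 7577300L, consequence = "inframe_indel"))
  gl <- data.frame(chrom = "chr17", pos = 7577100L, ref = "C", alt = "T")
  ann <- apply_annotation_rules(obs, gl, cfg)
  expect_equal(ann$germline_pass, c(FALSE, TRUE, TRUE))
  expect_equal(ann$consequence_pass, c(TRUE, FALSE, TRUE))
  strict <- pipeline_config(accept_inframe_indel = FALSE)
  expect_false(apply_annotation_rules(obs, gl, strict)$consequence_pass[3])
})

test_that("candidate calling composes the rules with ordered reasons", {
  # hand enumeration: row 1 passes R1; row 2 is rescued via baseline; row 3
  # is a germline hit; row 4 is synonymous despite read support
  obs <- rbind(
    make_obs(pos = 100L, k_alt = 30L),
    make_obs(pos = 100L, timepoint = "preoperative", k_alt = 1L),
    make_obs(pos = 200L, k_alt = 40L),
    make_obs(pos = 300L, k_alt = 50L, consequence = "synonymous"))
  gl <- data.frame(chrom = "chr17", pos = 200L, ref = "C", alt = "T")
  calls <- call_candidates(obs, gl, cfg)
  expect_equal(calls$call_status, c("called", "called", "rejected",
                                    "rejected"))
  expect_equal(calls$rejection_reason[3:4], c("R4_germline",
                                              "R6_consequence"))
  expect_true(grepl("R2_rescue", calls$passed_rules[2]))
  # every input row appears exactly once
  expect_equal(nrow(calls), nrow(obs))

  mixed <- rbind(make_obs(), make_obs(patient_id = "P2"))
  expect_error(call_candidates(mixed, gl, cfg),
               class = "ctdnamrd_validation_error")
})

test_that("hotspot annotation needs matching protein change and >= 20 cases", {
  calls <- call_candidates(make_obs(k_alt = 30L), NULL, cfg)
  hs20 <- data.frame(chrom = "chr17", pos = 7577100L, ref = "C", alt = "T",
                     aa_change = "p.R175H", cosmic_count = 20L)
  expect_true(annotate_hotspots(calls, hs20, cfg)$is_hotspot)
  hs19 <- transform(hs20, cosmic_count = 19L)
  expect_false(annotate_hotspots(calls, hs19, cfg)$is_hotspot)
  hs_other_aa <- transform(hs20, aa_change = "p.R175L")
  expect_false(annotate_hotspots(calls, hs_other_aa, cfg)$is_hotspot)
})

test_that("calling is idempotent and monotone in its thresholds", {
  set.seed(14)
  co <- simulate_cohort(simulation_config(25, seed = 14))
  calls <- call_cohort(co$observations)
  recalls <- call_cohort(calls[, c(names(co$observations))])
  expect_equal(recalls$call_status, calls$call_status)
  expect_equal(recalls$rejection_reason, calls$rejection_reason)

  called_n <- function(config) sum(call_cohort(co$observations, NULL,
                                               config = config)$call_status ==
                                     "called")
  base_n <- called_n(pipeline_config())
  expect_lte(called_n(pipeline_config(maf_threshold = 1e-3)), base_n)
  expect_lte(called_n(pipeline_config(min_distinct_reads = 5L)), base_n)
})

test_that("WBC variants at 0.1% MAF are essentially always called at depth", {
  set.seed(77)
  rc <- sample_read_counts(rep(0.001, 3000), 30000)
  obs <- make_obs()[rep(1, 3000), ]
  obs$compartment <- "WBC"
  obs$k_alt <- rc$k_alt
  obs$n_distinct <- rc$n_distinct
  expect_gt(mean(apply_read_support_rule(obs, cfg)), 0.99)
})
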