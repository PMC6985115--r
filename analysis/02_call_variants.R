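#!/usr/bin/env Rscript
# Rule-based candidate calling on the simulated cohort, independently per
# compartment: read support (>=3 distinct pairs and >=0.05% MAF), the
# cross-timepoint rescue, germline exclusion and protein-altering
# consequence.

library(ctdnamrd)

obs <- read_variant_observations("results/cohort/observations.tsv")
calls <- call_cohort(obs, germline_catalog = NULL,
                     config = pipeline_config())
utils::write.table(calls, "results/calls.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat("rows called / rejected: ", sum(calls$call_status == "called"), "/",
    sum(calls$call_status == "rejected"), "\n")
cat("rejections by reason:\n")
print(table(calls$rejection_reason[calls$call_status == "rejected"]))
n_base_cf <- length(unique(calls$patient_id[
  calls$call_status == "called" & calls$compartment == "cfDNA" &
    calls$timepoint == "baseline"]))
n_base_wbc <- length(unique(calls$patient_id[
  calls$call_status == "called" & calls$compartment == "WBC"]))
cat("patients with baseline cfDNA calls:", n_base_cf, "\n")
cat("patients with baseline WBC calls:  ", n_base_wbc, "\n")
cat("written to results/calls.tsv\n")
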