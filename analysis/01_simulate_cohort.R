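#!/usr/bin/env Rscript
# Generate the synthetic matched cfDNA/WBC study cohort used by the
# downstream analyses: 200 patients, three timepoints, baseline WBC,
# ground-truth origin and MRD labels.

library(ctdnamrd)

cfg <- simulation_config(200, seed = 20240901)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")

obs <- cohort$observations
cat("patients:            ", cfg$n_patients, "\n")
cat("observation rows:    ", nrow(obs), "\n")
cat("  cfDNA / WBC:       ", sum(obs$compartment == "cfDNA"), "/",
    sum(obs$compartment == "WBC"), "\n")
cat("truth variant labels:\n")
print(table(cohort$truth$variants$origin))
cat("true postoperative MRD-positive patients:",
    sum(cohort$truth$patients$mrd_postoperative), "\n")
cat("written to results/cohort/\n")
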