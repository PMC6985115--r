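---
title: "Methods: tumor-naive ctDNA residual-disease analysis with WBC filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-naive ctDNA residual-disease analysis with WBC filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnamrd)
```

## The problem

Plasma cell-free DNA (cfDNA) of a cancer patient is overwhelmingly of
hematopoietic origin; the tumor-derived fraction (ctDNA) often sits at
mutant allele fractions (MAF) of 0.1-3%. Two obstacles dominate
tumor-naive liquid-biopsy analysis at this depth. First, raw sensitivity:
detecting a 0.1% variant demands on the order of 30,000 distinct
(deduplicated, error-corrected) read pairs of coverage. Second, and more
insidious, clonal hematopoiesis (CH): expanded blood-cell clones carry
somatic mutations — often in bona fide cancer genes such as *DNMT3A* and
*TP53* — that appear in cfDNA at exactly the MAF range expected of ctDNA.
Without a correction, CH variants masquerade as tumor signal and destroy
the prognostic meaning of "ctDNA detected".

This package implements a perioperative analysis built around that
correction: sequencing the patient's white blood cells (WBC) at baseline
and subtracting everything the WBC data explains, then asking — for
variants the WBC data does *not* explain — how strongly the read counts
favor a tumor origin. Downstream, per-sample detection status feeds
molecular-response classification across the baseline, preoperative and
postoperative timepoints of a neoadjuvant-therapy study, and the
clinical-association statistics (contingency with pathologic regression,
Kaplan-Meier/log-rank survival, lead time of molecular over clinical
recurrence).

## Candidate calling rules

The pipeline begins at distinct-read-pair count tables (one row per locus
per sample): `k_alt` altered pairs of `n_distinct` total. A row becomes a
candidate somatic mutation when

* **R1 (read support)** — `k_alt >= 3` *and* `k_alt / n_distinct >=
  0.05%`, both thresholds inclusive; or
* **R2 (rescue)** — `k_alt >= 1` here while the identical variant
  (chrom, pos, ref, alt) passes R1 at another timepoint of the same
  patient and compartment, past or future;

and additionally

* **R4 (germline)** — the key is absent from a dbSNP-style catalog of
  common germline variants;
* **R6 (consequence)** — the variant is protein-altering: missense,
  nonsense, frameshift or splice. In-frame indels also pass by default
  (`accept_inframe_indel`), since they are coding-altering events that
  demonstrably occur among true ctDNA calls; the toggle exists because
  the literal rule list omits them.

Misplaced-alignment/paralog artifacts (the classical rule between R4 and
R6) are handled by an optional user-supplied locus blacklist
(`pipeline_config(blacklist = ...)`, default empty): this pipeline starts
downstream of alignment and cannot re-derive alignment diagnostics.
Rejected rows carry the first failing rule in the order consequence,
germline, blacklist, read support, so rejection tallies are stable and
auditable. Hotspot status (nucleotide *and* protein change identical to a
catalog entry observed in >= 20 cancer cases) is an annotation, never a
calling criterion. WBC samples are called with the same rules; the rescue
rule simply never fires when only one WBC timepoint exists, which also
settles the open design question of whether WBC calling should look
across timepoints — it does, whenever multiple WBC timepoints are
provided.

Distinct-read totals are taken as per-position values supplied by
upstream processing; nothing in the model requires a per-amplicon
interpretation.

## WBC subtraction and the origin model

**Hard filter.** A called cfDNA variant whose key carries >= 1 altered
distinct read in the patient's baseline WBC sample is classed
hematopoietic. One read is deliberately aggressive: at 30,000x WBC depth
a true CH variant at theta >= 0.1% is WBC-positive with probability
`1 - (1-0.001)^30000`, i.e. essentially always, so the filter's
sensitivity is excellent and its cost (an occasional tumor variant lost
to a stray WBC read) is the conservative direction for an MRD assay.

**Bayes factor for WBC-negative variants.** For a variant with `k_cf` of
`n_cf` altered cfDNA pairs and 0 of `n_wbc` WBC pairs, both compartments
are modeled as binomial draws with unknown allele fraction theta, under
two hypotheses:

* tumor-derived: `theta_WBC = 0`, `theta_cfDNA ~ Beta(2.4, 340)`;
* hematopoietic: `theta_WBC = theta_cfDNA ~ Beta(2.4, 340)`.

The Beta(2.4, 340) prior is equivalent to having seen 2.4 altered reads
per 340 molecules (prior mean ~0.7%), loosely matched to the MAF range of
variants seen in both compartments; the shapes are treated as fixed
constants because no refit procedure is defined for them. Integrating
theta out gives beta-binomial marginal likelihoods

```
log m_T = log C(n_cf, k_cf) + log B(k_cf + a, n_cf - k_cf + b)          - log B(a, b)
log m_H = log C(n_cf, k_cf) + log B(k_cf + a, n_cf - k_cf + n_wbc + b)  - log B(a, b)
```

whose ratio `BF = m_T / m_H` is, with prior odds 1, the posterior odds;
the reported probability is `BF / (1 + BF)`. Three consequences worth
internalizing: `BF >= 1` whenever `n_wbc > 0` (a clean WBC readout can
only ever *support* tumor origin, by monotonicity of the Beta function in
its second argument); the probability is exactly 0.5 at `n_wbc = 0` (no
discriminating evidence); and any altered WBC read forces probability 0,
because the tumor model assigns it zero likelihood — which is also why
the hard filter and the model agree by construction.

The closed form is the default engine. The sampling estimator — draw many
thetas from the prior, average the per-draw data probabilities — is
retained as `marginal_likelihood_monte_carlo()` both as an alternative
engine and as the standing cross-check; it shares theta draws between the
two models, so the posterior probability carries a paired delta-method
Monte Carlo standard error, and 1e5 seeded draws is the default ("large"
is otherwise unquantified). All likelihood arithmetic is in log space and
finite for counts to 1e6; probabilities are assembled with `plogis` to
avoid overflow at extreme Bayes factors.

`n_wbc` for a variant never observed in WBC data is the WBC distinct
coverage at that position when a coverage row exists, else the patient's
median WBC coverage, else 0 (probability 0.5): the model needs a WBC
denominator and this fallback degrades gracefully toward "no evidence".

Detection status itself is governed by the hard filter; the posterior
annotates variants. `p_min` (default 0 = off) can additionally require a
minimum posterior for detection, but no such cutoff is part of the
default analysis.

## Fragment lengths

Tumor-derived cfDNA fragments run shorter than hematopoietic or wild-type
fragments. The package compares empirical length CDFs of the three origin
classes with two-sample Kolmogorov-Smirnov tests, pooling fragments
across patients by default (`by_patient = TRUE` stratifies). The D
statistic is the exact sup-distance in every case. For the p-value the
exact two-sample null distribution is used when `n1 * n2 <= 10000` and
the asymptotic Kolmogorov distribution (effective n = n1 n2/(n1+n2))
beyond: at the 100-vs-100 scale the two coincide (both reject at
D >= 0.20, true size 3.64% at nominal 5% — the discreteness of D makes
5% unreachable exactly), while at genuinely small n the exact form is
better calibrated and costs microseconds.

## Outcome statistics

* **Molecular response** per patient from baseline/preoperative
  detection: `cleared`, `persistent`, `emergent`, `never_detected`;
  postoperative status (when sampled) is the MRD readout.
* **Fisher's exact test** (two-sided, fixed margins) backs the 2x2
  associations; the odds ratio is the cross-product with a 0.5
  continuity correction when a cell is empty. Enumeration ties are
  compared at relative tolerance 1e-7.
* **Concordance with pathologic regression**: a resected patient is
  concordant when TRG 1-4 (any regression) pairs with undetected ctDNA
  or TRG 5 (no regression) with detected ctDNA. The contingency
  dichotomy defaults to TRG 1-4 vs 5 — the dichotomy under which the
  concordance definition lives — with TRG 1-2 vs 3-5 (responders vs the
  rest) exposed as an option; on the reference strata both land at
  p = 0.03 to two decimals.
* **Survival**: Kaplan-Meier product-limit curves (median = first time
  the curve reaches 0.5, else "not reached"), the standard log-rank
  test, and an O/E (Mantel-Haenszel-style) hazard ratio
  `HR = (O1/E1)/(O0/E0)` with log-variance `1/E1 + 1/E0`. O/E was chosen
  over a Cox fit because it is self-contained, auditable against the
  log-rank risk tables, and behaves sanely in the tiny-stratum settings
  this analysis meets; a Cox model is a one-liner with `survival` for
  anyone wanting the cross-check. Survival comparisons include every
  patient with a status at the relevant timepoint (resected or not);
  restricting to resected patients is a matter of subsetting the
  clinical table before the call.
* **Lead time**: recurrence month minus postoperative-sample month over
  patients with postoperative detection and observed recurrence; the
  cohort summary is the median.

## The synthetic cohort generator

`simulate_cohort()` generates matched cohorts with the statistical
structure the analysis assumes, plus ground truth, so every stage is
testable without access to patient-level data. Per patient:

* age ~ Uniform(40, 80); Lauren subtype (intestinal/diffuse/other with
  weights 0.48/0.48/0.04); treatment arm at random.
* CH burden ~ Poisson with mean `0.05 * exp(0.05 * age)` — an
  exponential age relation, ~1 expected CH variant at age 60. The
  observed age dependence in WBC data is a fit (r-squared scale), not a
  generative law, so these two constants are free parameters of the
  generator, recoverable by Poisson regression in the tests.
* CH allele fractions lognormal(log 0.003, 0.9) — centered at 0.3% MAF
  with an interquartile spread matching the ~0.18-0.63% range typical of
  deep WBC sequencing; each CH variant appears in baseline WBC *and* in
  cfDNA at all three timepoints at the same underlying theta.
* Tumor shedding gated per subtype (0.75 intestinal / 0.40 diffuse /
  0.50 other — intestinal tumors shed detectably more often);
  shedders carry Poisson(2), minimum 1, tumor variants with theta
  lognormal(log 0.003, 0.8) truncated at 0.1%, the reliable-detection
  scale of a 30,000x assay.
* Therapy response: 30% of patients are pathologic responders (TRG 1-2,
  vs 3-5 otherwise); shedders clear their ctDNA by the preoperative
  draw with probability 0.9 (responders) or 0.15 (non-responders);
  non-cleared patients remain MRD-positive after surgery with
  probability 0.6. Cleared means theta = 0 from that timepoint on — and
  the generator then emits *no* row, matching an assay that reports
  observed loci only.
* Coverage ~ Poisson(30,000) truncated at 1 per row
  (`wbc_coverage_mean` lets the WBC libraries run shallower, which is
  the regime where the Bayes model earns its keep because CH variants
  start escaping the one-read filter).
* Low-level artifacts (theta 3e-5, single timepoint, mean 1 per cfDNA
  sample) exercise the rejection path of the caller.
* Outcomes: recurrence ~ Exponential with monthly hazard 0.08 when
  truly MRD-positive after surgery and 0.004 otherwise (a ~20-fold
  hazard contrast, the scale a strong MRD marker shows); death follows
  recurrence after an Exponential(mean 12 months) delay; administrative
  censoring at 48 months, near a ~42-month median follow-up. EFS/OS
  fields derive from these, so EFS <= OS whenever both events occur.
* Fragment lengths: Normal, mean 145 bp (tumor) vs 167 bp (other),
  sd 25, rounded and truncated positive — the mononucleosomal mode with
  the tumor shift placed at the canonical ~20 bp; the generator exposes
  all three numbers because no reference means are established.

What the generator does **not** emulate: sequencing-error substitution
spectra (artifacts are a flat low-theta class), panel capture bias, UMI
family-size structure, clonal evolution between timepoints (theta is
piecewise constant), emergent-resistance dynamics (emergent molecular
responses arise only from sampling noise), or correlated multi-variant
shedding within a tumor. Passing tests therefore demonstrate that the
*analysis* is correct and well calibrated under its own model, not that
the model captures every failure mode of real plasma sequencing.

## Numerical and testing choices

* Coordinates are 1-based, fully closed; indel alleles are explicit
  left-anchored strings so keys match across samples.
* MAF is stored as a fraction and rendered as percent in reports.
* Zero-coverage rows fail R1 rather than erroring; empty WBC tables keep
  all cfDNA calls with a warning (degraded, not silent).
* The Monte Carlo engine rejects fewer than 100 draws outright.
* Test problem sizes: 200-patient cohorts for recovery properties,
  150 patients for the survival-contrast property, 500 patients for CH
  slope recovery, 1e5 Monte Carlo draws on a 24-point (k, n, n_wbc)
  grid, 4000-rep KS null calibration and 500-permutation log-rank
  calibration — sizes chosen so each property estimate is comfortably
  more precise than the tolerance it is checked against.
* Independent oracles in the test suite: adaptive quadrature
  (Laplace-windowed) for the marginal likelihoods, full hypergeometric
  enumeration for Fisher p-values, brute-force sup-distance for KS D,
  and hand-tabulated risk sets for log-rank/HR.

## Known limitations

The origin model sees one variant at a time; it does not pool evidence
across timepoints or across a patient's variant set, and it models no
third "sequencing artifact" class — artifact suppression rests entirely
on the calling rules. The O/E hazard ratio is biased away from 1 in
small, heavily censored strata relative to a Cox partial-likelihood
estimate; its CI is approximate. The hard one-read WBC filter will
misclassify a truly tumor-derived variant that happens to draw a WBC
read (e.g. low-level tumor DNA in the buffy coat); the posterior is
reported precisely so such calls can be revisited. Cohort-scale
headline numbers from any specific patient series (positivity rates,
median MAFs, specific hazard ratios) depend on that series' data and are
not reproduced here; the package's claims are the structural and
calibration properties its tests compute.
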