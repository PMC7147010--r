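---
title: "Comparing early warning scores: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing early warning scores: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewscompare)
```

## The problem

Track-and-trigger systems score routine vital signs — systolic blood
pressure, heart rate, temperature, respiratory rate, oxygen saturation and
level of consciousness — on small integer scales and add the points into an
aggregate early warning score (EWS). `ewscompare` implements three such
systems and the machinery needed to compare their ability to discriminate
short-term mortality in an emergency-department (ED) cohort:

* **TOKS**, the Central Denmark Region score (six components, maximum 18,
  no points for supplemental oxygen);
* **mTOKS**, TOKS plus a flat 2 points whenever the patient receives
  supplemental oxygen (maximum 20);
* **NEWS**, the Royal College of Physicians 2012 National Early Warning
  Score (maximum 20, including 2 oxygen points).

The scientific question the package is built around is whether the oxygen
supplement carries prognostic information that the measured vitals do not:
oxygen therapy corrects saturation and lowers respiratory rate, so a treated
patient can present deceptively reassuring numbers while the underlying
condition persists.

## Scoring model

### Tables are data, not code

Each system is a JSON file (`inst/extdata/scores/`) holding one ordered set
of threshold bands per vital parameter, a level-of-consciousness (LOC) rule
and the oxygen weight. This was a deliberate design choice: published
scoring tables are typeset artifacts, and flattened transcriptions of such
tables can misalign a band with its points column. Keeping the tables as
data makes the transcription auditable and correctable without touching
code, and `validate_score_system()` enforces two checksums that the
publications state outright:

* every scale must partition the real line with no gaps or overlaps and
  exactly one zero band;
* the maximum attainable aggregate score recomputed from the bands must
  equal the declared maximum (18 / 20 / 20).

Where the flattened TOKS table leaves a column assignment ambiguous (the
systolic band at and above 200 mmHg, the left-hand heart-rate and
temperature bands, the respiratory-rate weights), the shipped config uses
the weights conventional in comparable scores (e.g. 2 points for severe
hypertension, NEWS-like respiratory weights). Any revision against the
typeset original is a one-line JSON edit, and the checksum guards against
edits that break the printed maxima.

### Interval convention

All bands are half-open, `[lower, upper)`: a measurement exactly on a
threshold scores in the band that threshold opens. This matches the
"≥ a – < b" notation the tables use. Open ends are encoded as JSON `null`
and become infinite bounds internally.

### Level of consciousness and agitation

TOKS scores AVPU as A = 0, V = 1, P = 2, U = 3 with one extra point for
agitation, combined by *maximum*. The maximum rule (rather than a sum) is
forced by the published ceiling: six components with a 3-point worst band
give exactly 18 only if agitation cannot add on top of U. The combination
is configurable (`"sum"`) so an additive variant is one config edit. NEWS
maps any non-alert level to 3 and has no agitation modifier.

At ED triage, consciousness is recorded as a Glasgow Coma Scale total and
converted: GCS 15 = A, 14 = V, 9–13 = P, ≤ 8 = U (`gcs_to_avpu()`). GCS
does not capture agitation, so when LOC comes from a GCS value the engine
zeroes the agitation flag — reproducing what the measurement process can
actually see. `honor_agitation_with_gcs = TRUE` overrides this for
sensitivity analysis.

### Saturation granularity

Saturation is accepted as a real number; integer recording is the common
case but nothing in the scales requires it.

## Cohort construction

`build_cohort()` applies, in a fixed order, with every encounter counted
under the first applicable reason only:

1. eligibility: age < 16, elective admission, registered healthy
   companion, missing national identifier;
2. first contact: per patient, only the earliest arrival is kept
   (identical timestamps resolve stably to the first record, with a
   warning);
3. index vitals: the earliest record within 4 h of arrival (boundary
   inclusive, measured from the arrival timestamp) in which all six
   parameters *and* the oxygen-supplement status are documented. Oxygen
   documentation is part of completeness because a score including oxygen
   points cannot be computed without it; encounters lacking *only* that
   field are sub-counted separately so the cost of the requirement is
   visible in the flow report.

The outcome is death within seven *calendar* days, day zero being the
arrival day, i.e. date offsets 0 through 7 inclusive. The boundary is a
parameter (`followup_days`) because "within seven days, day zero being the
first day" admits both a ≤ 6 and a ≤ 7 reading; the package fixes ≤ 7 as
the default and exposes the knob. A death date before arrival is treated as
a data-integrity error, not silently censored. The window origin (arrival
rather than triage start) is likewise a deliberate fixed choice: it is the
only timestamp guaranteed to exist for every encounter.

A reserved optional column for "do not resuscitate" status exists in the
schema but is not acted on — the data needed to use it are typically not
exportable, and its absence is a known source of pessimism in discrimination
estimates.

## Discrimination analysis

`auroc()` computes the tie-corrected Mann–Whitney statistic — the
probability that a random case outscores a random control with half credit
for ties — which equals the trapezoidal area under the empirical ROC curve
of `compute_roc()`. Half-credit tie handling is essential here: scores are
small integers (max 18–20), so ties are the norm, not an edge case.

The variance uses DeLong's structural components. For case *i* the
placement $V_{10,i}$ is the fraction of controls it outranks (half credit
for ties), and symmetrically $V_{01,j}$ for controls; then

$$\widehat{\mathrm{var}}(\hat\theta) = \frac{S_{10}}{m} + \frac{S_{01}}{n}$$

with $S_{10}, S_{01}$ the sample variances of the placements. Placements
are computed with midranks in $O(N \log N)$ and retained in the returned
object, so covariances between scores measured on the same subjects are
formed directly. `paired_delong_test()` refers
$\delta^2/\widehat{\mathrm{var}}(\delta)$ to $\chi^2_1$;
`compare_systems()` runs the three pairwise tests plus an optional global
2-df contrast that all three AUROCs are equal.

Design choices made where the analysis was genuinely open:

* **Confidence intervals** are Wald intervals on the AUROC scale using the
  DeLong standard error, clipped to [0, 1]; a logit-scale interval is
  available via `ci_method = "logit"`. No CI method is canonical for this
  statistic; Wald-with-clipping is the most common default and is what the
  interval widths of comparable reports imply.
* **Multiplicity**: the three pairwise tests are reported at a single
  α = 0.05 without adjustment, mirroring how paired EWS comparisons are
  conventionally reported; the global contrast is available when a single
  omnibus answer is wanted.
* **Direction** is fixed: higher score means higher predicted risk. No
  automatic flipping is performed, so an AUROC below 0.5 is reported as
  such.

### Small-sample behaviour of the paired test

The chi-square reference is asymptotic. With very few cases the variance of
the AUROC difference is estimated from that many placement values, and the
statistic behaves like a squared *t* with roughly (cases − 1) degrees of
freedom treated as normal: at 10 cases the true type-I error of the nominal
5% test is about 8–9% (cf. $P(|t_9| > 1.96) \approx 0.08$), converging to
5% by roughly 50–100 cases. The test suite demonstrates both facts. This is
a property of the estimator itself, not of this implementation — users
comparing scores on cohorts with a handful of events should expect the
paired test to be anti-conservative there.

## The synthetic cohort

Real regional-registry data of this kind cannot be redistributed, so the
package ships a generator (`generate_cohort()`) whose default configuration
*is* the stated world the analysis targets. One latent severity per
encounter drives correlated vital derangement (BP down, heart and
respiratory rate up, temperature in either direction, saturation down,
consciousness down), agitation, oxygen administration, documentation and
mortality. Two strata set the case mix: a young "minor injury" stratum with
near-zero severity whose vitals frequently go unmeasured, and an older
"medical" stratum. Specific modelling decisions:

* **Unmeasured frailty.** Mortality is logistic in severity *plus* a
  patient-level frailty term no vital sign can see (chronic comorbidity
  burden). Without it, any reasonable vital-response model makes the
  integer scores near-perfect predictors (AUROC > 0.9); with frailty
  SD 2.2 the scores land in the moderate-to-good range (TOKS ≈ 0.77,
  mTOKS ≈ 0.80, NEWS ≈ 0.79 at the defaults) that mortality-prediction
  studies actually report.
* **Oxygen as signal.** Oxygen is prescribed on severity *and* on frailty
  (clinicians see the chronically ill), and when given, observed
  saturation and respiratory rate are pulled 70% of the way back toward
  baseline — the masking mechanism that motivates compensatory oxygen
  points. Together these make the oxygen flag genuinely informative beyond
  the measured vitals: the default world yields an mTOKS − TOKS AUROC gain
  of ≈ +0.02 to +0.04, positive in essentially every replicate at
  n = 20 000.
* **Missingness is not at random marginally, but is given acuity.**
  Documentation probability rises with severity and with frailty, so the
  excluded group is younger and far less likely to die — matching the
  included-versus-excluded contrast of the motivating cohort (~2% vs
  ~0.2% 7-day mortality, median ages ~61 vs ~41). A small share of
  incomplete records lack only the oxygen field, and some encounters get
  their first complete set only after the 4-h window, so both exclusion
  paths are exercised.
* **Repeat visits** occur for ~8% of patients, 10–80 days after the first
  contact; the death draw happens at the last visit so no record can
  postdate a death. The corollary — repeat patients cannot die within a
  week of their *first* visit — is absorbed by the mortality calibration
  and is irrelevant at the default repeat rate.
* **Calibration.** Free parameters (mortality intercept, documentation
  intercepts, age-mixture shapes) were tuned once against the stated
  margins — 52% female, 2% included mortality, ~63% included, median age
  61 (IQR 41–76) — and frozen. They are not adjusted per run or per seed.

What the generator does **not** emulate: real joint vital-sign
distributions, true oxygen-prescription policy, seasonal or site effects,
measurement rounding habits, and any absolute AUROC of a real registry.
Consequently a green test establishes that the pipeline and estimators
behave correctly in a world with the stated structure — not that the
numerical results of any particular registry are reproduced.

## Numerical and degenerate-input choices

* Band lookup uses `findInterval` on the lower bounds, giving exact
  half-open semantics with no floating-point window.
* `compute_roc`/`auroc` refuse degenerate outcome vectors (no cases or no
  controls) with an informative error rather than returning NaN.
* A paired test with zero estimated variance returns p = 1 when the
  difference is also zero (identical scores) and errors otherwise.
* Ties in arrival or measurement timestamps resolve stably in favour of
  the first record, with a warning for arrivals, so reruns are
  reproducible on identical input order.
* All generator randomness flows from one integer seed; identical config
  and seed give byte-identical CSV output.

## Known limitations

* The TOKS band-to-column transcription carries the documented
  ambiguities; the checksums bound, but cannot eliminate, transcription
  risk.
* The paired chi-square test is anti-conservative below ~50 cases (see
  above).
* The Wald CI can touch the boundary for near-separating scores; use the
  logit interval there.
* The generator's latent-severity structure is deliberately simple; it is
  a test harness and a power-analysis sandbox, not an epidemiological
  model of any real ED population.
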