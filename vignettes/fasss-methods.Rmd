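---
title: "Scoring fat lesions in the spondyloarthritis spine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring fat lesions in the spondyloarthritis spine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasss)
```

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. It covers the anatomy
model, the scoring arithmetic, the reliability statistics, the synthetic
cohort generator, and the numerical conventions. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The anatomy model

FASSS scores focal fat lesions per **disco-vertebral unit** (DVU), the
region between the horizontal midplanes of two adjacent vertebrae on
sagittal T1-weighted MRI. Twenty-four vertebral levels (C2 … S1) bound 23
DVUs, C2/C3 through L5/S1. Each DVU has a *cranial* endplate (the lower
endplate of its upper vertebra) and a *caudal* endplate (the upper endplate
of its lower vertebra); the package keys every site by the DVU-relative
endplate label, which maps bijectively to the vertebra-relative phrasing
("upper endplate of L3" = caudal endplate of L2/L3). One unambiguous key
per site makes duplicate detection and reader comparison trivial.

Per endplate the central sagittal slices carry an anterior corner, a
posterior corner and a noncorner site; thoracic and lumbar DVUs add lateral
corner sites (left and right, anterior and posterior, per endplate).
Noncorner lesions are scored only on central slices, and the cervical spine
has no lateral slices — the pedicles there sit lateral to the vertebral
body, so both structures never appear on one sagittal slice. That yields 14
sites per thoracolumbar DVU, 6 per cervical DVU, 274 over the whole spine.

**Segment attribution of the transitional DVUs.** The published per-DVU
maxima (24 thoracolumbar, 8 cervical) and the global ceiling of 456 are
consistent only with a 6/12/5 split: cervical C2/C3–C7/T1, thoracic
T1/T2–T12/L1, lumbar L1/L2–L5/S1, since 6×8 + 17×24 = 456 while a
5-cervical split would give 472. The package therefore scores C7/T1 under
cervical rules and T12/L1 under thoracic rules, and uses the same partition
for segmental sums. Whether the original segmental tabulations used exactly
this attribution for the transitional units is not stated anywhere we can
check; the forced partition is the only one compatible with the printed
arithmetic, and the test suite asserts the 456 identity.

## Scoring arithmetic

Site weights: corner lesions score 1 (central or lateral); thoracolumbar
*central* corner lesions add +1 when large (≥25% of the endplate's
anterior–posterior diameter and/or the vertebral body height); noncorner
lesions score 2, +2 when large (≥25% of body height). Cervical lesions and
lateral corner lesions carry presence only. Annotation input is sparse:
only observed lesions are rows, absence scores 0.

**Combined lesions.** A central corner lesion spanning more than 50% of the
AP diameter is a *combined* corner-and-noncorner lesion. The source
definition specifies its size additions (+1 if ≥25% of height at the
anterior/posterior cortex, +2 if ≥25% of height at the endplate midpoint)
but never prints the base arithmetic. The package scores it as corner base
1 (+1 cortex addition) plus a noncorner credit of 2 (+2 midpoint addition)
attributed to the endplate's noncorner site. This is the only reading we
found under which the per-endplate central maximum of 8 — and hence the
printed 16-central/8-lateral decomposition of the DVU maximum of 24 — is
attainable and cannot be exceeded. Both additions may co-occur on one
lesion; the per-endplate cap below keeps the arithmetic consistent either
way.

**Noncorner deduplication.** Per endplate, the noncorner component is
counted once: a direct noncorner annotation and the noncorner credits of
any combined corner lesions compete, and the largest credit wins.
Without this rule a reader marking both a >50% corner lesion and a separate
noncorner lesion on the same endplate would push the DVU past its printed
maximum.

**Exclusions.** DVUs whose disc height is unequivocally reduced by ≥50%
are not assessed (fat there may be degenerative). Excluded DVUs score 0
but stay in every output with a flag rather than being dropped, so
longitudinal and between-reader alignment is preserved. Annotating a
lesion on an excluded DVU is a validation error. The source does not state
how exclusion enters totals; contributing 0 is the conservative choice and
keeps the score's range interpretation intact.

**Cervical grading.** Cervical sites accept only `present`. In particular
the combined category is rejected at validation for cervical DVUs — the
definition of combined lesions is tied to the size assessment that is
explicitly not performed in the cervical spine, though the source is
silent on the conceptual case.

Scores are integers throughout; the engine never rounds. `score_exam()`
validates first and refuses to score an exam with violations;
`validate_annotations()` returns all violations as data (site id plus
problem) so batch pipelines can report everything at once. A vectorised
scorer computes all 23 DVUs in one pass; the simple per-DVU path
(`score_dvu()`) is retained and the test suite asserts the two agree on
random annotation sets, alongside property tests for monotonicity (adding
an annotation never lowers any component), additivity and the per-DVU
caps.

## Reliability statistics

**ICC.** `icc_a1()` implements the single-measure absolute-agreement
intraclass correlation from the two-way model with patients as the random
factor and readers as the fixed factor:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

with mean squares computed from explicit sums of squares. The 95%
confidence interval uses the F-distribution method for this ICC form with
Satterthwaite degrees of freedom for the denominator (the McGraw–Wong
convention); the source analysis names only "95% CI", and this is the
standard interval for the absolute-agreement single-measure form. Banding:
<0.4 fair, 0.4–<0.6 moderate, 0.6–<0.8 good, 0.8–<0.9 very good, ≥0.9
excellent, boundaries belonging to the upper band. A matrix with zero
total variance has no defined ICC and returns a flagged degenerate result
instead of raising, so stratified batch analyses complete. When the
readers agree cell-for-cell the error sum of squares is set to exactly
zero if it is zero up to summation-order rounding, making perfect
agreement return exactly 1. The test suite checks the implementation
against an independent ANOVA route (`stats::anova` on the two-way linear
model) to 10^-10 across a grid of random small matrices, and checks
invariance under common affine transforms.

**Bland–Altman and SDC.** `bland_altman()` returns the mean and sample SD
(denominator n−1) of the paired differences and limits at
mean ± z·SD with z the standard-normal quantile at (1+coverage)/2 —
1.2816 at the 80% coverage used for smallest-detectable-change estimation,
1.9600 at 95%. The smallest detectable change is

$$\mathrm{SDC} = \frac{z \cdot SD(\Delta_1 - \Delta_2)}{\sqrt{2}}$$

on the two readers' change scores. The √2 divisor (difference of k = 2
readings) and z are explicit, overridable arguments and are echoed in the
result, because the cited derivation of this convention is not reproduced
in the source text; the default is our declared convention, not an
assertion about the original arithmetic. SDC is invariant to a common
constant shift of both readers' change scores and scales linearly —
both are property-tested.

**Stratification.** `stratified_reliability()` assigns each patient pair
to exactly one inter-scan-interval stratum — defaults (0, 1.0], (1.0, 1.5],
(1.5, 2.0], (2.0, ∞) years, lower bounds exclusive — and reports per
stratum the n, per-reader descriptives, baseline ICC, change ICC and SDC.
Strata with fewer than two pairs are reported with their n and a
degenerate flag.

**Discrepancy adjudication.** `flag_discrepant()` applies three
pre-specified rules to paired change scores: (A) absolute difference ≥10
*and* relative difference >100% of the pair's mean change; (B) changes in
opposite directions at ≤−2 and ≥2; (C) exactly one reader scoring no
change while the other's change has magnitude ≥3. Rule A's denominator
when the pair mean is 0 is unstated in the source; we evaluate the
relative criterion division-free as |d₁−d₂| > |(d₁+d₂)/2|, under which a
zero mean with a nonzero difference satisfies it. The suite checks the
implementation against a literal per-pair transcription of the rules on
the exhaustive integer grid [−15, 15]².

**Conventions.** Quartiles use linear interpolation between order
statistics (`stats::quantile` type 7); cumulative probability plots use
plotting positions (i − 0.5)/n on ascending values, ties keeping their
individual points. Neither convention is specified by the source; both are
fixed here and documented so external reanalyses can match them.

## The synthetic cohort generator

No annotation-level data are published for any real reading exercise, so
validation uses a generator whose statistical structure mirrors what the
reliability analysis assumes.

**Truth model.** Patient i draws a latent severity
$s_i \sim \mathrm{LogNormal}(\mu, \sigma)$; a site is prevalent at baseline
with probability $1 - \exp(-s_i\, w_{\mathrm{seg}}\, w_{\mathrm{type}})$.
Prevalent thoracolumbar central lesions are large with probability
`p_large` and, if corner and large-track, combined with probability
`p_combined`. At follow-up (inter-scan interval uniform on
[`interval_min`, `interval_max`], default [0.5, 3.0] years so all four
interval strata are populated) each lesion persists unless it regresses
(`p_regress`, default 0.05 — fat lesions mostly persist, but observed
cohorts do show score decreases in a minority of patients), and a Poisson
number of new lesions accrues with rate
`accrual_rate × interval × s_i / E[s]`, allocated to empty sites
proportionally to the same weights. Tying the accrual rate to severity is a design choice — it makes the more
affected patients the likelier progressors, which matches how structural
progression behaves clinically. Excluded DVUs are
drawn per patient (`p_excluded_dvu`), fixed across timepoints, and never
host lesions.

**Reader model.** Conditional on the truth, each reader records a true
lesion with probability `sensitivity`, annotates an empty site with
probability `false_positive_rate`, and flips small↔large with probability
`p_size_misgrade` where size applies. False positives are recorded at the
minimal grade for their site class — the error channel has no ground truth
for the size of a hallucinated lesion. Errors are independent Bernoulli
across sites, exams and readers (no spatial correlation); that is the
simplest channel sufficient for ICC/SDC recovery, and it is the main
respect in which the generator is *less* adversarial than real readers,
whose disagreements cluster anatomically and correlate with image quality.
Passing recovery tests therefore demonstrates the pipeline's correctness,
not the field reliability of any real reading. Two seed streams (cohort
seed; cohort seed + per-reader offset) make readers conditionally
independent and every output a pure function of (parameters, seed).

**Default calibration.** Defaults are calibrated to the regime the
observational tables describe:
severity log-normal with meanlog = log(0.045) and sdlog = 1.3, segment
weights 1.0/0.9/0.5 (thoracic/lumbar/cervical), site-type weights
1.0/0.5/0.7 (central corner/noncorner/lateral), `p_large` 0.3,
`p_combined` 0.15, accrual 2 lesions/year, `p_regress` 0.05,
`p_excluded_dvu` 0.01. Under these defaults a 135-patient cohort read with
plausible reader error (sensitivity 0.9, false-positive rate 0.005,
misgrade 0.1) produces baseline totals with mean in the low 20s, SD of
similar magnitude, a heavily right-skewed distribution, segment means
ordered thoracic > lumbar > cervical, and change-score ICC/SDC in the
published ballpark. Only the segment *ordering* is asserted in tests; the
magnitudes depend on per-site prevalences that no published table pins
down, so the calibration is documented as non-authoritative.

## Numerical and interface choices

- DVU codes are `"upper/lower"` strings (`"T12/L1"`); parser and formatter
  round-trip exactly, and unknown codes error with the offending string.
- Annotation and score-sheet CSV dialects are fixed (see
  `read_annotations()` / `write_scoresheets()`); write-then-read is the
  identity on exams, and malformed rows are reported with file line
  numbers.
- Reliability reports serialise statistics at 4 decimal places for
  reproducible diffs; scores are integers everywhere.
- `exam_time_years` is decimal years from baseline; intervals are computed
  from the two exam times, never user-supplied, when both timepoints are
  present.
- Because annotation input is sparse, an exam with no findings has no rows;
  workflows that must keep such exams (any two-reader comparison) pass an
  explicit exam roster (`exam_grid`) so lesion-free exams score 0 instead
  of vanishing.

**Problem sizes.** The test suite exercises ICC oracle equivalence on
matrices up to 6×3, variance-component recovery at n = 135 with 200
replicates, discrepancy rules on the exhaustive 961-pair grid, and
simulator properties on cohorts of 5–80 patients with up to 12 replicates
per condition; these sizes give stable orderings and tight oracle
agreement while keeping the default suite quick to run.

## Known limitations

- The package scores annotations, not images: slice classification
  (central vs lateral), lesion detection and size judgement are reader
  tasks upstream of this code.
- Inflammation (STIR) lesions, erosions, ankylosis and sacroiliac anatomy
  are out of scope, as are responsiveness statistics beyond those listed.
- The empirical reliability of the original two-reader exercises cannot be
  reproduced here — that would require the readers' raw scores, which were
  never published. What the package validates is the arithmetic of the
  score and the correctness of the statistical machinery against
  independent oracles and simulations with known parameters.
- The reader-error model is site-independent; extending it with spatially
  correlated errors (per-DVU or per-segment random effects) is the natural
  next step if one wants to stress the statistics under more realistic
  disagreement patterns.
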