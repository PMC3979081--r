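# fasss

Scoring and reader-reliability analysis for the **FAt Spondyloarthritis
Spine Score (FASSS)** — an anatomy-based semi-quantitative scoring system
for focal fat lesions on T1-weighted sagittal spine MRI in axial
spondyloarthritis. Fat lesions (fat metaplasia) mark sites of resolved
inflammation and are a candidate intermediary between inflammation and new
bone formation, which makes a reliable quantitative score of them useful as
an imaging outcome in clinical studies.

The package is for imaging researchers and methodologists who work with
*structured lesion annotations* (which reader saw which lesion where), not
with DICOM pixels: it scores annotations, quantifies how well two readers
agree, and simulates annotation data with known properties so the whole
pipeline can be validated end to end.

## The score

The spine from C2 to S1 is divided into 23 **disco-vertebral units**
(DVUs), C2/C3 through L5/S1 — each the region between the midplanes of two
adjacent vertebrae. Within a DVU, fat lesions are scored per endplate and
anatomical site:

| site | where | score |
|---|---|---|
| corner lesion, central slice | anterior/posterior corner of either endplate | 1, +1 if large (≥25% of AP diameter or body height; thoracic/lumbar only) |
| noncorner lesion | central slice, endplate between the corners | 2, +2 if large (≥25% of body height; thoracic/lumbar only) |
| lateral corner lesion | lateral slices, thoracic/lumbar only | 1 (no size weighting) |
| combined corner-and-noncorner lesion | central corner lesion spanning >50% of the AP diameter | corner part 1 (+1 if large at the cortex) plus noncorner credit 2 (+2 if large at the endplate midpoint) |

Cervical lesions are not graded for size, and the cervical spine has no
lateral slices. Each thoracic/lumbar DVU therefore ranges 0–24 (central
slices at most 16, lateral slices at most 8), each cervical DVU 0–8, and
the total score 0–456. DVUs with unequivocal disc-height loss of ≥50% are
excluded (scored 0 and flagged), since fat there may be degenerative.

## Reliability toolkit

The statistical half mirrors how such scores are validated in
multi-reader exercises:

- `icc_a1()` — intraclass correlation from a two-way model (patients
  random, readers fixed), *single measures, absolute agreement*, with
  F-based 95% CI and the qualitative banding fair / moderate / good /
  very good / excellent (cuts at 0.4, 0.6, 0.8, 0.9);
- `bland_altman()` — limits of agreement at configurable coverage
  (default 80%, z = 1.2816);
- `sdc()` — smallest detectable change, `z · SD(d)/√2` on the two
  readers' change-score differences;
- `stratified_reliability()` — the same statistics stratified by
  inter-scan interval (≤1.0, >1.0–1.5, >1.5–2.0, >2.0 years);
- `flag_discrepant()` — the pre-specified adjudication rules for
  discrepant change scores (absolute difference ≥10 together with a
  relative difference >100% of the pair mean; opposite directions at
  ≤−2 / ≥2; one reader 0 while the other is ≥3 in magnitude);
- `cumulative_probability_points()`, `descriptives()` — plotting
  coordinates and summaries.

A synthetic cohort generator (`simulate_truth()`, `simulate_reader()`,
`recovery_experiment()`) draws per-patient latent severity, places lesions
with segment-dependent prevalence (thoracic > lumbar > cervical),
progresses them over a follow-up interval, and passes them through a
configurable reader error channel — so ICC/SDC recovery can be tested
against known ground truth.

## Worked example

The packaged fixture encodes a published single-slice example: small
anterior corner lesions at the upper endplates of T12, L1, L2 and L3, and
one large anterior corner lesion at the lower endplate of L2.

```r
library(fasss)
fixture <- system.file("extdata", "worked_example_annotations.csv", package = "fasss")
exam <- read_annotations(fixture)[[1]]
score_exam(exam)
#> FASSS score sheet: patient example, t = 0 y, reader r1
#>   total 6 (cervical 0, thoracic 2, lumbar 4)
#>   nonzero DVUs: T11/T12=1, T12/L1=1, L1/L2=1, L2/L3=3
```

Each small corner lesion contributes 1 to its DVU; the large lesion at the
lower endplate of L2 contributes 2, so L2/L3 (which also holds the small
lesion at the upper endplate of L3) scores 3 and the T12–L3 span sums to 6.

Reliability statistics work on any paired score vectors:

```r
m <- cbind(r1 = c(12, 30, 2, 41, 9, 25), r2 = c(14, 27, 2, 44, 7, 28))
icc_a1(m)
#> ICC(A,1) = 0.9873, 95% CI (0.9183 to 0.9982), excellent; n = 6 subjects, k = 2 readers
sdc(c(4, -2, 0, 9, 1, 3), c(6, -1, 0, 7, 2, 3))
#> SDC = 1.2381 (z = 1.2816 at 80% coverage, SD(diff) = 1.3663, n = 6)
```

A command-line interface wrapping these functions ships in
`inst/cli/fasss.R` with subcommands `score`, `change`, `reliability`,
`flag-discrepant` and `simulate`; see the header of that file for usage.

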