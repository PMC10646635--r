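---
title: "Methods: subchondral QIB measurement, SPARCC arithmetic and responsiveness statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subchondral QIB measurement, SPARCC arithmetic and responsiveness statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beachsij)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Everything stated here is either implemented and
tested in the package or explicitly marked as a limitation; no empirical
claim is made that the test suite does not itself compute.

## The measurement model

Bone marrow oedema in active sacroiliitis raises the apparent diffusion
coefficient (ADC, reported here in 10⁻⁶ mm²/s) of subchondral marrow and
displaces marrow fat, lowering the proton density fat fraction (PDFF, %);
post-inflammatory fat metaplasia raises PDFF. The package quantifies both
from parameter maps through a semi-automated chain:

1. An observer draws the joint line as an **open polygon** (≥ 2 vertices, in
   mm) and two **anchor lines** that fix the angle the joint makes with the
   cortex at each end (`joint_delineation()`).
2. `propagate_rois()` offsets the polyline perpendicular by `depth_mm`
   (default **10 mm**) toward each side, producing one sacral and one iliac
   polygon that share the polyline as a common boundary. Joins between
   segments are **mitred**, with a miter limit of 2 × depth beyond which the
   join is bevelled; the same limit applies to the anchor-directed end
   edges, which otherwise run parallel to the anchor lines. A joint curving
   tighter than the offset depth folds the offset chain onto itself; this is
   detected as a proper self-intersection of the ROI polygon and raised as
   an error naming the offending vertex.
3. `rasterize_polygon()` marks a pixel as inside iff its **centre** is
   inside the polygon, with centres exactly on the boundary counted as
   inside (a deterministic tie rule; see *Numerical choices*).
4. `pool_pixels()` concatenates masked map values over both joints, both
   sides and the included slices: **all synovial slices for ADC** and
   **alternate slices for PDFF** (PDFF maps are acquired at much thinner
   slices). Only slices flagged synovial contribute; the ligamentous
   portion of the joint is excluded by construction.
5. `compute_metrics()` reports the mean and the 25th/50th/75th/90th
   percentiles of the pooled distribution — the QIBs ADC_25 … ADC_90 and
   PDFF_25 … PDFF_90.

### SPARCC arithmetic

`score_bme()` sums per-quadrant oedema flags over 6 consecutive slices × 2
joints × 4 quadrants, plus one point per joint per slice if the oedema is
more than 10 mm deep and one if it is at least as intense as CSF. The
depth/intensity increments are scored **per joint per slice, not per
quadrant**: only that reading makes the canonical maximum come out at
6 × 2 × (4 + 1 + 1) = 72, which the scoring of a fully flagged annotation
reproduces exactly. The fat component (`score_sss_fat()`) counts fat
quadrant flags over the structural slice set; the default 6 × 2 × 4
configuration has maximum 48, and the slice set is configurable through the
shape of the annotation because the fat maximum is not uniquely decomposable
into a slice–joint–quadrant product in the source descriptions of the
score. Bonus flags without any involved quadrant in their joint-slice are
rejected at construction.

### Responsiveness and agreement statistics

With pre/post measurements averaged over readers (`average_readers()`):

* paired *t* test on the change Δ = pre − post (`paired_t()`), 95% CI
  = mean(Δ) ± t₀.₉₇₅,ₙ₋₁·SE;
* **SRM** = mean(Δ)/SD(Δ) with sample SD (n − 1), banded on magnitude as
  negligible (< 0.2), small (0.2–0.5), moderate (0.5–0.8), large (≥ 0.8),
  half-open upward (`srm()`);
* `srm_from_summary()` inverts the CI: SE = (CI width)/(2·t₀.₉₇₅,ₙ₋₁),
  SD = SE·√n, SRM = (mean_pre − mean_post)/SD. The round-trip identity
  srm(Δ) == srm_from_summary(means, CI, n) holds to 10⁻⁹ and is tested;
* Bland–Altman agreement with a **fixed 1.96 multiplier** (not a *t*
  quantile), matching standard practice for 95% limits of agreement
  (`bland_altman()`);
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measure — computed from the ANOVA mean squares (`icc()`). The variant is
  a declared package choice: reliability reports rarely name one, and
  ICC(2,1) is the conservative option for interchangeable readers;
* single-predictor binary logistic regression by IRLS (tolerance 10⁻⁸, 100
  iterations), with perfect separation raised as an error instead of an
  estimate (`logistic_response()`);
* clinical response flags exactly per the stated inequalities: boundary
  values 1.2/1 are responders (≥), ΔASDAS = 1.1 and post ASDAS = 1.3 are
  not (strict > and <) (`classify_clinical_response()`).

Change-sign convention: change = pre − post for ADC, SPARCC and clinical
scores (improvement positive); PDFF change is reported post − pre because
PDFF rises as oedema resolves. No multiple-testing correction is applied
across metrics, mirroring how such responsiveness tables are usually
reported; treat per-metric p values accordingly.

## The synthetic cohort generator

`generate_cohort()` exists so the full chain can be exercised and validated
without patient data. Its defaults are the study conditions the analysis
assumes, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 30 | typical biologic-therapy cohort size |
| `n_slices`, grid | 6 × 80 × 80 px, 1.5 mm, 3 mm thick | covers both joints plus > 10 mm margins |
| marrow ADC | mean 195, SD 60 | pooled baseline ADC median lands near 195 |
| marrow PDFF | mean 57%, SD 10% | pooled baseline PDFF median near 57% |
| oedema shift | +300 ADC, −30% PDFF (peak) | focal oedema well above marrow background |
| fat-lesion shift | +25% PDFF | fat metaplasia |
| lesion counts/radii | 0–3 oedema, 0–2 fat per joint; 3–8 mm | mixed-activity cohort incl. lesion-free joints |
| `lesion_max_depth_mm` | 15 | anatomic subchondral bone is deeper than the 10 mm sampling ROI, so the SPARCC > 10 mm depth bonus is a live event |
| `treatment_effect` | 0.5 | oedema intensity and radius halved post treatment; fat lesions unchanged |
| `reader_jitter_sd_mm` | 1 | plausible vertex placement noise between trained readers |
| rater sens/spec | 0.90 / 0.95 | experienced-rater quadrant calls |
| spinal VAS change | mean 2.14, SD 2.52 | planted clinical effect (SRM ≈ 0.85); BASDAI/ASDAS/CRP magnitudes analogous |

Joints are gently curved, roughly vertical open polylines (5 vertices, small
per-slice shifts); lesions are spherical intensity offsets with a parabolic
profile, combined across overlapping lesions by maximum (saturating) and
clipped to the subchondral band, so PDFF never leaves [0, 100]. Baseline
noise fields are rejection-sampled inside the physical bounds, which keeps
the lesion offsets strictly monotone: every oedema voxel has higher ADC and
lower PDFF than its lesion-free twin except where PDFF saturates at 0.

Clinical change scores are drawn **exactly** at the configured mean/SD; the
baseline is then drawn from a truncated normal conditioned so that both
visits stay inside the score's range. This ordering matters: clamping the
post score instead would distort the change distribution and bias the
planted SRM upward by several percent. In the rare case that a drawn change
exceeds the whole scale width it is clamped to that width. Correlation
between imaging change and clinical change defaults to 0 (independent
draws), consistent with cohorts in which the two do not correlate; a
Gaussian-copula coupling to the oedema-burden change is available via
`imaging_clinical_correlation`.

One global seed drives everything; per-patient and per-role substreams are
derived by fixed offsets, so any single patient (or reader, or rater) can be
regenerated alone, and two runs with the same config are byte-identical.

**What the generator does not emulate.** Real acquisition physics (fat–water
separation, diffusion-weighting, ghosting), partial-volume and chemical-shift
artefacts, zero-inflated ADC backgrounds (real cohorts show ADC_25 values
near zero that a single Gaussian marrow model cannot produce), anatomic
joint shape beyond a curved polyline, erosions/ankylosis, and — importantly —
**between-visit measurement variability** beyond fresh voxel noise: the same
true geometry and lesion centres are re-used pre/post, so synthetic imaging
SRMs come out larger than published ones. Passing the recovery tests
therefore demonstrates correctness of the measurement and statistics chain
under the generator's assumptions, not that real-world responsiveness would
match.

A simulated reader jitters every vertex isotropically (SD
`reader_jitter_sd_mm`) and rotates the anchors by a proportional angle
(SD = jitter/10 rad); a delineation whose offset folds back at the
requested depth is redrawn, as an interactive reader whose contour the tool
rejects would. A simulated visual rater calls each truly involved quadrant
with probability `sensitivity` and each uninvolved one with
`1 − specificity`, carrying over depth/intensity flags only where at least
one quadrant was called.

## Numerical choices

* **Percentiles**: linear interpolation of the empirical quantile (R type 7).
  The convention is configurable (`quantile_type`) because it shifts values
  on small samples; published descriptions of histographic QIBs rarely
  state one.
* **Boundary pixels** count as inside, ties resolved toward inclusion, so
  masks are identical across platforms; where the rasterized sacral and
  iliac masks share a pixel centre exactly on the joint line, the pixel is
  counted once (sacral side).
* **Coordinates**: continuous mm, origin at the centre of pixel (1, 1);
  pixel (r, c) centre at ((r−1)·Δr, (c−1)·Δc).
* **Histogram export**: uniform bins, defaults 64 bins over [0, 1200] for
  ADC and [0, 100] for PDFF; out-of-range values are counted in the end
  bins so totals are conserved.
* **Degenerate inputs** fail loudly: empty pixel samples, zero-variance
  changes, incomplete rating matrices, single-class outcomes and separable
  logistic fits are errors, not numbers.
* **Alternate-slice start**: PDFF slice selection starts at the *first*
  synovial slice; the alternative (second slice) is an equally defensible
  reading and can be had by shifting the synovial range.

## Problem sizes used in the validation suite

The Monte-Carlo checks are sized to give comfortable statistical margins at
interactive runtimes: planted-SRM recovery uses 200 cohorts of n = 30
(clinical component only — the spinal-VAS SRM does not depend on imaging;
the mean estimate is expected near 0.872, the small-sample expectation of
mean/SD at n = 30 for a true δ of 0.849, well inside the ±0.05 acceptance
band around 0.85); the jitter→agreement experiment uses 200 patients at 3
slices with jitter levels 0.5/2/4 mm; rasterization is checked against an
exhaustive point-in-polygon oracle on 100 random joints; rater-noise
expectation is checked against exact enumeration at 10⁴ replicates.

## Known limitations

* The ROI propagation assumes an approximately monotone joint line; hairpin
  geometries are rejected rather than resolved.
* The fat structural score maximum (48 by default) is configuration, not
  ground truth; published totals ("out of 50") do not decompose cleanly.
* `srm_from_summary()` assumes the printed CI is a paired-*t* interval for
  the same n as stated; rows printed with other conventions (or with
  transcription errors) are flagged inconsistent rather than repaired.
* ICC assumes a complete patients × readers matrix; unbalanced designs are
  out of scope.
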