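---
title: "Methods: semi-quantitative perfusion analysis and the synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-quantitative perfusion analysis and the synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfquant)
```

## The measurement model

First-pass perfusion CMR acquires a dynamic short-axis stack while a
gadolinium bolus transits the heart. Signal in a myocardial region rises
at a rate that, over the early upslope, is approximately proportional to
regional blood flow; the semi-quantitative workflow therefore reduces each
region to the steepest slope of its time–signal-intensity (TSI) curve.

For each of the 16 AHA segments and for a blood-pool ROI we compute, per
state (rest, stress):

1. **Baseline and bolus arrival** — the baseline is the mean of the first
   `n_baseline` frames; enhancement begins at the first frame exceeding
   baseline + 3·SD of those frames. A noise-free baseline has SD 0, for
   which we substitute an absolute tolerance of 1 au so the rule remains
   usable on synthetic data.
2. **Maximum upslope** — an ordinary least-squares line is fitted to every
   contiguous window of `k` frames that starts at or after bolus arrival
   and ends no later than one frame past the curve's global peak; the
   maximum fitted slope (au/s) is kept, with ties resolved to the earliest
   window. Bounding the search at the peak excludes recirculation; OLS
   slopes are shift-invariant, so no baseline subtraction is applied.
3. **Relative upslope** — segment upslope divided by blood-pool upslope,
   removing the dependence on bolus amplitude, injection rate and global
   signal scale. A non-positive blood-pool upslope is an error (degenerate
   input), never an infinity.
4. **MPRI** — the stress/rest ratio of relative upslopes per segment;
   level means over basal (1–6), mid (7–12) and apical (13–16) segments;
   global MPRI as the arithmetic mean of available segments (with `n`
   recorded, in case segments are excluded upstream).

The key assumption is that the upslope is measured during pure wash-in,
before contrast recirculation, and that the blood-pool curve is a valid
common reference for all segments of a state.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` (upslope window) | 3 | frames | short windows track fast pediatric bolus dynamics; 2 is noisier, 5+ smooths past the true maximum slope |
| `n_baseline` | 5 | frames | enough frames for a stable baseline SD at 1 s resolution |
| deficit `threshold` | 0.75 | fraction of median | a segment is flagged when its within-state relative upslope falls below 75% of the state median; an automated surrogate for the visual call |
| `max_shift` | 5 | px | registration search half-width; generous for in-plane respiratory drift at 1–3 mm pixels |
| blood-pool erosion | 2 | px | avoids partial-volume pixels at the endocardial edge |

## Geometry conventions

Contours are simple polygons in a 0-based pixel frame (x right, y down,
pixel centres at integers); rasterisation uses the even–odd rule on pixel
centres. Segments are assigned by angle about the endocardial centroid,
with angle zero on the ray toward the RV-insertion landmark and sectors
advancing with increasing `atan2(dy, dx)`; basal/mid slices get six
60-degree sectors, apical slices four 90-degree sectors. Pixels exactly on
a sector boundary go to the lower-numbered segment — an arbitrary but
frozen tie-break that makes masks bit-reproducible. Any consistent angular
convention yields identical MPRI statistics, since every segment is
treated symmetrically; this one is fixed so tests can assert exact masks.

Papillary polygons are subtracted from the annulus before labelling, and
no additional myocardial erosion is applied before TSI extraction (a
documented choice; commercial packages do not publish theirs).

LV volumes use summation of discs (endocardial area × slice increment),
end diastole/systole by max/min volume — there is no ECG in scope — and
Mosteller BSA, `sqrt(height·weight/3600)`, for indexing.

## The synthetic phantom

The phantom exists so that every downstream stage has closed-form ground
truth:

- **Arterial input**: an amplitude-normalised gamma-variate,
  `s0 + A·((t−t0)/(αβ))^α · exp(α − (t−t0)/β)`, peaking at exactly
  `s0 + A` at `t = t0 + αβ`. Defaults: A = 100 au, t0 = 8 s, α = 3,
  β = 2 s, s0 = 50 au — a bolus with ~6 s rise time, plausible for a
  pediatric injection, and identical at rest and stress.
- **Tissue**: pure uptake, `S = s0_myo + F·dt·cumsum(aif − s0_blood)`,
  i.e. no washout during the simulated window. The maximum instantaneous
  tissue slope is then `F·A`, so the relative upslope is proportional to
  `F` and the true MPRI equals `F_stress/F_rest` exactly when both states
  share the AIF shape. First-pass upslope metrics are insensitive to
  washout, which justifies the simplification.
- **Geometry**: three slices (base, mid, apex) of concentric-circle
  annuli, endo 10 mm / epi 16 mm at 1 mm pixels on a 64×64 grid, apical
  radii scaled by 0.7 (the apex is smaller; the factor is configurable and
  not a claim about anatomy).
- **Flows**: `F_rest = 0.1`, `F_stress = 0.2` per segment by default — a
  uniform two-fold reserve. Reversible deficits are reduced `F_stress`
  entries; fixed deficits reduce both states.
- **Timing**: dt = 1 s, 60 frames, 5 baseline frames. Acquisition frame
  rates vary by protocol; these defaults are configurable choices, not
  claims about any study.
- **Noise**: additive Gaussian, default σ = 1 au (~0.7% of peak signal).
  Real magnitude MRI noise is Rician, but in the enhancement regime SNR is
  high and the Gaussian approximation is standard; this is a documented
  limitation, not an oversight.
- **Motion**: an integer random-walk in-plane translation (amplitude
  ≤ `motion_amplitude` px), applied identically to all slices of a frame
  and recorded in the truth block. Integer motion is exactly recoverable
  by the integer-shift registration stage, which gives the pipeline a
  clean recovery property; it does not model through-plane motion or
  deformation.
- **Dark rim** (optional, off by default): a one-pixel subendocardial ring
  at 80% of tissue enhancement during bolus transit in both states,
  mimicking the qualitative phenotype of the dark-rim artifact. Detecting
  it is a human/qualitative task and out of scope.

What passing phantom tests shows: the geometry, extraction, slope, ratio
and registration code are correct against analytic truth. What it does not
show: robustness to surface-coil shading, saturation of the AIF at high
contrast dose, deformable motion, arrhythmia, or real tissue kinetics —
conclusions about patient data still require patient data.

## Statistical layer

- **Welch t-test**, computed from group means/SDs/sizes (raw samples are
  reduced first). "Unpaired t-test" is underspecified; Welch is the safer
  default under unequal variances and is the frozen choice.
- **Wilcoxon rank-sum** with midrank ties: exact two-sided p by
  enumerating the permutation distribution of the rank sum (a subset-sum
  recursion over doubled midranks — integers, so tie comparisons are
  exact) for total n ≤ 20; otherwise the normal approximation with the
  standard tie-corrected variance and no continuity correction (a frozen
  choice; with it, p-values differ by at most one lattice step).
- **Bland–Altman**: bias, sample-SD limits `bias ± 1.96·SD(d)`, and COV
  defined as the within-subject SD `SD(d)/√2` over the grand mean of all
  measurements, in percent. COV conventions vary; this one is frozen and
  documented so users can convert to alternatives.
- **ICC(2,1)**: two-way random effects, absolute agreement, single
  measurement, from the subjects × raters ANOVA mean squares, with the
  standard F-based confidence interval. Zero between-subject variance
  yields a warning and ICC 0 rather than 0/0.
- **Percent change**: `100·(peak − baseline)/baseline` per subject, with
  cohort mean ± SD via `group_summary()`.

## Defect classification

The decision table is a pure function of three booleans per segment:

| stress deficit | rest deficit | LGE | call |
|---|---|---|---|
| yes | no  | –   | reversible |
| yes | yes | yes | fixed |
| yes | yes | no  | artifact |
| no  | no  | –   | normal |
| no  | yes | –   | artifact |

The rest-only row has no established physiological reading (a true
perfusion deficit should not vanish under vasodilation); it is mapped to
"artifact" as the package's own extrapolation and surfaced as such in the
output, so downstream users can treat it specially.

## Numerical and degenerate-input choices

- Slope ties (two windows within 1e-12 au/s) resolve to the earlier
  window; registration score ties resolve to the smallest shift, so an
  aligned frame is never moved.
- Empty segment masks, flat (bolus-free) curves, non-positive blood-pool
  or rest upslopes, endo ⊄ epi contours, and missing landmarks all raise
  errors naming the offending entity — the pipeline fails loudly rather
  than emitting NaN/Inf.
- All randomness (noise, motion, simulated cohorts) flows from the single
  spec/config seed; repeated runs are byte-identical.

## Problem sizes used in the test suite

Unit tests run a reduced phantom (48×48 px, 40 frames) where full
resolution adds nothing; end-to-end property checks use the default
64×64 × 60-frame, 3-slice phantom. Stochastic properties (noise
monotonicity, shift recovery, registration benefit, ICC recovery) use 20
replicate seeds; the upslope estimator is checked against exhaustive
window enumeration on 200 randomized curves, and the rank-sum test against
full permutation enumeration for every group-size combination with total
n ≤ 12. These sizes are the package's chosen trade-off between coverage
and a test suite that stays fast enough to run on every change.

## Known limitations

- Semi-quantitative only: no Fermi or model-based deconvolution, hence no
  absolute myocardial blood flow (mL/min/g).
- Gaussian (not Rician) noise; rigid integer (not deformable) motion.
- Contours are inputs; there is no automatic myocardial segmentation.
- The blood-pool ROI is taken from one designated slice (default mid),
  mirroring single-ROI practice; slice-wise AIFs are not modelled.
- ED/ES selection by volume extrema assumes the contoured phases bracket
  the true extremes.
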