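# perfquant

Semi-quantitative analysis of first-pass myocardial stress perfusion
cardiac MRI, with a fully synthetic phantom for validation.

Stress perfusion CMR images the first transit of a gadolinium bolus
through the left-ventricular myocardium at rest and under pharmacologic
vasodilator stress. Hypoperfused territory enhances more slowly, which is
captured semi-quantitatively from the time–signal-intensity (TSI) curve of
each AHA segment: the **maximum upslope** is the steepest rate of signal
rise (au/s), the **relative upslope** normalises it by the blood-pool
upslope,

    relative upslope = max upslope(segment) / max upslope(blood pool),

and the **myocardial perfusion reserve index** is the stress-to-rest ratio
per segment,

    MPRI_s = relative upslope_s(stress) / relative upslope_s(rest),

with the global MPRI the mean over the 16 segments. The package is aimed
at imaging researchers who want these quantities — and their agreement
statistics (Bland–Altman limits, coefficient of variation, ICC(2,1)) — as
tested, scriptable building blocks rather than a vendor workstation.

Because no patient images ship with tools like this, `perfquant` includes
a synthetic rest/stress phantom: a gamma-variate arterial input function
fills the LV lumen, each AHA segment follows a pure-uptake tissue curve
scaled by a known flow `F`, and noise plus integer in-plane motion can be
added. With the same bolus shape at both states the true MPRI is exactly
`F_stress / F_rest`, so every stage of the pipeline can be checked against
closed-form ground truth.

## What is in the box

- `phantom_spec()` / `generate_phantom()` / `write_phantom()` — synthetic
  4D rest/stress series (NIfTI), contours (JSON) and ground truth.
- `segment_aha16()`, `rasterize_annulus()`, `lv_volumes()` — AHA
  16-segment masks from endo/epi contours plus the RV-insertion landmark;
  summation-of-discs LV volumes, LVEF, Mosteller-indexed LVEDVi.
- `register_frames()`, `extract_tsi()`, `max_upslope()`,
  `relative_upslope()`, `compute_mpri()`, `classify_defect()`,
  `flag_deficit_segments()` — the quantification core.
- `welch_ttest()`, `wilcoxon_rank_sum()` (exact, midrank ties),
  `bland_altman()`, `icc_absolute()`, `percent_change()` — the
  statistical layer.
- `run_pipeline()` and a thin CLI (`inst/scripts/perfquant.R`) with
  `simulate | quantify | run` subcommands.

## Worked example

A phantom with a two-fold flow reserve everywhere except segment 8, whose
stress flow is halved (a reversible, stress-only deficit), with 1 au
Gaussian noise:

```r
library(perfquant)

f_stress <- rep(0.2, 16); f_stress[8] <- 0.1
spec <- phantom_spec(noise_sigma = 1, f_stress = f_stress, seed = 9)
ph <- generate_phantom(spec)

masks <- lapply(ph$contours, segment_aha16, grid = dim(ph$rest$data)[1:2])
mpri <- compute_mpri(extract_tsi(ph$rest, masks, state = "rest"),
                     extract_tsi(ph$stress, masks, state = "stress"))
mpri
#> MPRI result over 16 AHA segments
#>   global MPRI: 1.944
#>   level means: basal 2.009  mid 1.835  apical 2.010

round(mpri$segments$mpri[mpri$segments$segment == 8], 3)
#> [1] 1.011

flags <- flag_deficit_segments(mpri$segments$relupslope_stress)
table(classify_defect(flags,
                      flag_deficit_segments(mpri$segments$relupslope_rest),
                      rep(FALSE, 16)))
#>     normal reversible
#>         15          1
```

The unaffected segments sit near the true reserve of 2.0 (dragging the
mid-level mean down is segment 8 itself, whose MPRI of about 1.0 is half
the others — exactly the injected deficit), and the automated deficit
flagging plus the defect decision table call that one segment reversible.

The same analysis from a shell:

```sh
Rscript inst/scripts/perfquant.R run --out phantom_demo --seed 9
```

## Documentation

The methods vignette (`vignettes/perfusion-methods.Rmd`) describes the
model and its assumptions, what the phantom does and does not emulate,
every tunable parameter with its default and rationale, and known
limitations.
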