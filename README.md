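# petquant

Quantification of dynamic brain PET with reversible radiotracers, built
around the question every blood-hungry tracer eventually faces: how
much of the arterial sampling and how many of the 90 scan minutes are
actually needed?

The package implements, as tested reusable components:

* **Arterial input-function construction** — cross-calibration of
  continuous and discrete whole-blood records, plasma-over-blood
  conversion, monotone-spline tail extension, and sigmoid
  parent-fraction (metabolite) correction, yielding a continuous
  parent-plasma input function (ppIF) on a 1-s grid.
* **Classic spectral analysis** — voxelwise non-negative decomposition
  of tissue curves into input-convolved exponentials,

  $$C_T(t) \approx \sum_j \alpha_j\, C_p \otimes e^{-\beta_j t},
  \qquad \alpha_j \ge 0, \qquad V_T = \sum_j \alpha_j/\beta_j,$$

  on a 100-point log-spaced rate grid between 1/5100 and 1/5 s⁻¹, with
  an optional whole-blood vascular column and blood-volume-corrected
  volume-of-distribution ($V_T$) images.
* **SUV epochs** — standardised uptake values over frame-aligned
  post-injection windows (default: 20–30 … 80–90, 30–60, 60–90 min).
* **Population-based input functions (PBIFs)** — weight/dose/age
  magnitude normalisation, 80-s peak alignment, pointwise median, and
  rescaling to an individual via an AUC-vs-single-late-plasma-sample
  regression (leave-one-out by default).
* **Scan-duration truncation** — shortened datasets re-fitted with
  duration-matched spectral slow boundaries
  (0.000290/0.000256/0.000222/0.000196 s⁻¹ for 60/70/80/90 min).
* **Agreement statistics** — pooled and per-region Spearman ρ with
  Fisher-z CIs, Bland–Altman bias and limits of agreement, percent
  differences, and between-subject coefficients of variation.
* **A seeded synthetic cohort** with known two-tissue-compartment
  ground truth (closed-form $V_T = (K_1/k_2)(1+k_3/k_4)$), so the whole
  pipeline is validated end to end against analytic oracles.

File formats: NIfTI for images (4-D dynamic, 3-D parametric, integer
ROI label maps), a JSON sidecar for frame timing, CSV for blood tables,
metadata, input functions and results tables.

## Worked example

```r
library(petquant)

res <- run_pipeline(list(
  out_dir = "study", seed = 1, n_participants = 20,
  variants = c("ppif-90", "ppif-60", "pbif-90", "suv-80-90")))

res$reports[["pbif-90"]]
#> <agreement_report> pbif-90 vs ppif-90 (140 pairs)
#>   pooled rho 0.934 (95% CI 0.909-0.952)
#>   bias 0.392, LoA [-1.595, 2.378], mean % diff 3.54%
#>   mean delta BS-CV 0.82 pp

res$reports[["ppif-60"]]
#> <agreement_report> ppif-60 vs ppif-90 (140 pairs)
#>   pooled rho 0.960 (95% CI 0.945-0.971)
#>   bias -0.726, LoA [-2.172, 0.720], mean % diff -6.67%
#>   mean delta BS-CV 0.61 pp
```

Reading: on a 20-participant synthetic cohort (7 regions, so 140 pooled
data points), PBIF-derived $V_T$ ranks participants and regions almost
identically to the full arterial method (ρ = 0.93) but adds
between-subject variability (BS-CV up by ~0.8 percentage points), while
cutting the scan to 60 min keeps ρ = 0.96 at the cost of a systematic
−6.7% bias, concentrated in the regions with the slowest kinetics —
both directions mirroring what is reported for real cohorts. `study/`
contains per-variant regional CSV tables, a ground-truth table, and
JSON + CSV agreement reports for each variant against `ppif-90`.

A thin CLI over the same functions (subcommands `simulate`, `ppif`,
`sa`, `suv`, `truncate`, `compare`, `run`) is installed at
`inst/cli/petquant.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/petquant.R", package="petquant"))')" \
    run --config study.json
```

## Package layout

```
R/                  implementation (curves, schedules, I/O, synthetic
                    cohort, input functions, spectral analysis, SUV,
                    PBIF, truncation, agreement, pipeline)
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette: models, assumptions, validation
scripts/            acceptance.R (see above)
inst/cli/           command-line front end
```
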