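---
title: "Quantifying dynamic PET without full arterial sampling: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic PET without full arterial sampling: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petquant)
```

## The problem

Fully quantitative brain PET with a reversible radiotracer reports the
total volume of distribution, $V_T$: the equilibrium ratio of tracer
concentration in tissue to the concentration of unmetabolised (parent)
tracer in arterial plasma. Estimating $V_T$ requires (a) a long dynamic
acquisition (here 90 min) and (b) the arterial parent-plasma input
function (ppIF), which in turn requires arterial cannulation, continuous
blood counting, discrete samples, plasma separation and metabolite
analysis. Both requirements limit clinical use, especially for tracers —
such as NMDA-receptor ligands — with no reference region devoid of
target.

`petquant` implements the full quantification pipeline and the two
families of simplification it is natural to evaluate against it:

1. **SUV epochs** — blood-free standardised uptake values over late
   post-injection windows;
2. **population-based input functions (PBIFs)** — a standardised cohort
   input-function shape rescaled to an individual using a single late
   plasma sample;
3. **shortened acquisitions** — $V_T$ from 60/70/80-min data with the
   full input function.

Because real raw data of this kind are rarely shareable, the package
ships a synthetic-cohort generator with known compartmental ground
truth, so that every stage of the pipeline can be validated end to end
and the agreement machinery exercised under controlled conditions.

## The input-function pipeline

The ppIF is built from two blood records in four steps
(`build_ppif()`):

1. **Cross-calibration** (`cross_calibrate()`). The continuous detector
   (0–15 min, ~1 s resolution) and the well counter used for discrete
   samples are reconciled by a single multiplicative scalar, fitted by
   least squares over all discrete whole-blood samples inside the
   continuous window. Negative detector values (background-subtraction
   noise) are clamped to zero first and counted.
2. **Plasma conversion** (`apply_plasma_over_blood()`). The
   plasma-over-blood ratio measured at paired discrete samples is
   linearly interpolated over time (held constant beyond the first/last
   ratio sample) and applied pointwise.
3. **Tail extension** (`merge_continuous_discrete()`). Beyond the
   continuous window the plasma curve is continued through the late
   discrete plasma samples with a shape-preserving monotone cubic
   interpolant (`splinefun(method = "monoH.FC")`), anchored at the
   continuous curve's end. A monotone-safe interpolant is used because
   an unconstrained cubic can undershoot below zero between sparse
   decaying samples; activity is non-negative by definition.
4. **Metabolite correction** (`fit_parent_fraction()`). The parent
   fraction is modelled as a decreasing sigmoid constrained to 1 at
   injection,
   $f(t) = 1 - A\,t^h / (t^h + T_{50}^h)$,
   with drop amplitude $A \in [0,1]$, half-drop time $T_{50}$ (s) and
   Hill coefficient $h$. The fit is unweighted least squares; the
   optimiser works on $(\mathrm{logit}\,A, \log T_{50}, \log h)$ with a
   coarse-grid start, because the raw parameters differ by three orders
   of magnitude and box-constrained quasi-Newton steps stall on that
   scaling.

The result lives on a uniform 1-s grid from injection to the scan end.
The functional form of the sigmoid and the spline type are documented
modelling choices: only "a sigmoid normalised to unity at 0 min" and
"spline interpolation" are externally constrained.

## Spectral analysis

Classic spectral analysis (`spectral_fit()`) decomposes a tissue
time-activity curve into a non-negative sum of input-function-convolved
exponentials on a fixed rate grid:

$$C_T(t) \approx \sum_{j} \alpha_j \; C_p \otimes e^{-\beta_j t}, \qquad
\alpha_j \ge 0, \qquad V_T = \sum_j \alpha_j / \beta_j .$$

* **Rate grid** (`basis_grid()`): 100 log-spaced rates between the slow
  boundary $1/5100\,\mathrm{s} \approx 1.96\times10^{-4}\,$s$^{-1}$ and
  the fast boundary $1/5\,\mathrm{s} = 0.2\,$s$^{-1}$. One hundred
  basis rates make the grid-resolution error in $V_T$ far smaller than
  the 2% oracle tolerance used in the tests.
* **Convolution**: performed on the 1-s input grid by the exact
  recursion for trapezoidal quadrature (a C-level recursive filter),
  then averaged over each frame interval. Against adaptive quadrature
  this is accurate to better than 0.1% for the rate range used.
* **Solver**: non-negative least squares (Lawson–Hanson via
  `pracma::lsqnonneg`), with design-matrix columns scaled to unit norm
  purely for conditioning — raw activity-scale columns differ in norm
  by orders of magnitude across the rate grid and can stall the active
  set iteration.
* **Weights**: frame durations by default (uniform and
  duration/activity variants are available); pre-injection background
  frames get weight zero.
* **Vascular signal**: voxel data follow
  $(1-v_b)\,C_\mathrm{tissue} + v_b\,C_\mathrm{blood}$. By default the
  design matrix carries a whole-blood column (excluded from $V_T$).
  `vt_image()` then reports
  $V_T = \sum_j \alpha_j/\beta_j \,/\, (1 - \hat v_b)$, since the
  tissue amplitudes are attenuated by exactly $(1-v_b)$ under this
  signal model and the fitted vascular coefficient estimates $v_b$.
  The vascular curve is the participant's measured whole-blood record
  where available. This matters for PBIFs: the population curve is
  peak-realigned to a standard 80 s and is therefore mistimed relative
  to the voxel's true blood signal; using it as the vascular regressor
  turns a ~16-s timing offset into a ~9% $V_T$ error, whereas the
  participant's own blood record keeps the identity-cohort fixed point
  within spectral-analysis tolerance.

`vt_closed_form()` supplies the independent oracle,
$V_T = K_1/k_2$ (one-tissue) or $(K_1/k_2)(1 + k_3/k_4)$ (two-tissue);
on noise-free synthetic regions voxelwise spectral $V_T$ agrees with it
to within 0.1% (the tests assert 2%).

## SUVs, PBIFs and scan shortening

**SUV** (`suv_epoch()`): $\mathrm{SUV} = \bar C \cdot w / D$ with
$\bar C$ the duration-weighted mean decay-corrected activity (Bq/mL)
over a frame-aligned epoch, $w$ body weight in g and $D$ injected dose
in Bq. Body-weight normalisation is used (not lean mass or BSA),
consistent with weight being the covariate used elsewhere in the
pipeline. The standard epoch set is the seven 10-min epochs from 20–30
to 80–90 min plus 30–60 and 60–90 min.

**PBIF** (`pbif_cohort()`): training ppIFs are magnitude-normalised by
the cohort-median-over-participant ratios of weight, then injected
dose, then age (the factors commute, so the medians are computed once
from the raw covariates); each curve's peak is aligned to 80 s (peak
located after a 5-s moving average to avoid noise spikes; whole-grid-
step shifts; curves are truncated to the common support afterwards);
the standardised curve is the pointwise median. An individual's PBIF is
the standardised curve rescaled by the ratio of (AUC predicted from
their single late parent-plasma sample, via an OLS regression of
training AUCs on training anchor samples) to the standardised curve's
AUC. The protocol is leave-one-out by default: each participant's model
is built entirely from the other participants. Age normalisation can be
disabled (`use_age = FALSE`); it is retained by default because the
synthetic cohort (like the data it emulates) has an age-dependent
parent-fraction AUC.

**Scan shortening** (`truncation_study()`): frames ending after the cut
are dropped (the cut must fall on a frame boundary), and the spectral
basis is rebuilt with a duration-matched slow boundary —
$2.90\times10^{-4}$, $2.56\times10^{-4}$, $2.22\times10^{-4}$ s$^{-1}$
for 60, 70, 80 min — because a shortened scan cannot support spectral
components much slower than its own length. These boundary values
follow no closed formula, so unsupported durations require an explicit
boundary rather than a guessed interpolation. The full-length input
function is used for every duration; only the emission data are
truncated.

The mechanism behind the shortened-scan bias is visible in the basis
grid: a region whose slow kinetic eigen-rate lies below the shortened
scan's slow boundary cannot be represented and its $V_T$ is clipped
downward. Regions with slower kinetics (in the brain: medial temporal
structures) lose more, which reproduces the regionally variant negative
bias, ordered 60 < 70 < 80 < 90 min.

## Agreement statistics

`compare_variants()` reports, for any pair of quantification variants
on the same cohort: pooled Spearman's $\rho$ over all
participant × region cells (95% CI via the Fisher z-transform with
SE $=1/\sqrt{n-3}$; the CI method is a documented choice), per-region
$\rho$ (reported missing below 4 participants), Bland–Altman bias and
1.96 SD limits of agreement, mean percent difference relative to the
reference variant, and the between-subject coefficient of variation
(100·SD/mean across participants) per region and variant with its
difference. Group-level hypothesis testing (e.g. MANOVA on subgroup
with an age covariate) is deliberately exported as a tidy table for
external statistical software rather than re-implemented.

## The synthetic cohort

The generator (`cohort_spec()`, `make_cohort()`, `simulate_blood()`,
`simulate_dynamic()`) emulates the acquisition design the pipeline
expects: 90-min scans, injection 30 s after acquisition start, a
42-frame schedule (one 30-s pre-injection background frame; 10-s frames
early, 300-s frames late; every SUV-epoch and truncation boundary
frame-aligned), doses ~ Normal(187, 4) MBq, weights uniform 55–95 kg,
ages spanning 20–62 years, continuous blood counting 0–15 min and nine
discrete samples at 5–90.5 min.

Choices the generator makes where only qualitative features are
externally constrained:

* **Whole blood**: a gamma-variate first-pass peak (peak 55–75 s) plus
  two washout exponentials (time constants ~1200 s and ~6000 s, with
  ~20% lognormal between-subject scatter on fractions and time
  constants); the plasma-over-blood ratio rises slowly and linearly
  from ~1.04. The continuous detector record is stored in its own
  uncalibrated units (a participant-specific gain in 0.75–1.25) so that
  cross-calibration has real work to do.
* **Parent fraction**: the same sigmoid family the fitter assumes, with
  $A = 0.85$, $h = 1.3$, and $T_{50}$ decreasing by 8 s per year of age
  plus 110 s of participant scatter. Those two numbers set the expected
  cohort correlation between age and parent-fraction AUC to about
  −0.66; the tests check the sign across 100 seeds.
* **Kinetics**: seven bilateral grey-matter regions with two-tissue
  parameters chosen so closed-form $V_T$ targets lie at 9.9–12.7 and
  the slow eigen-rates straddle the shortened-scan boundaries (medial
  temporal regions slowest). A participant-level lognormal factor on
  $K_1$ (sdlog 0.23) produces ~23–26% between-subject CV in $V_T$.
  Fractional blood volume is 0.05 everywhere.
* **Noise**: discrete blood samples get 3% proportional Gaussian noise;
  image frames get mean-zero Gaussian noise with SD
  $\propto \sqrt{\mathrm{activity}/\mathrm{duration}}$ (a
  count-statistics proxy), scale 30 by default. The subgroup labels
  carry no simulated effect on binding: no external effect size exists
  to calibrate one, so subgroup comparisons are out of scope for the
  synthetic study.

What the generator does **not** emulate: scanner PSF, attenuation,
scatter, randoms, reconstruction artefacts, anatomically realistic
atlases, inter-regional kinetic heterogeneity beyond the seven blocks,
dispersion/delay of the continuous detector, or real between-subject
input-function shape families beyond the parametric scatter above.
Passing tests therefore demonstrate internal consistency and correct
implementation of each method — not that the simplified methods would
achieve the same agreement statistics on real data.

## Problem sizes and determinism

The default study runs 20 participants on a 6×6×6 block phantom
(64 labelled voxels), which keeps a full multi-variant run under a
minute on one CPU while leaving every method's behaviour visible;
larger phantoms only average more voxels per region. All generators
draw from streams derived deterministically from the cohort seed plus a
stage label and participant index, so any stage can be reproduced in
isolation and a repeated run is byte-identical.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(list(
  out_dir = "study", seed = 1, n_participants = 20,
  variants = c("ppif-90", "ppif-60", "pbif-90", "suv-80-90")))
res$reports[["pbif-90"]]
```

Numerical results for the default study conditions are computed by
`scripts/acceptance.R` and by the test suite; this vignette states none
that they do not compute.

## Known limitations

* The PBIF stage requires every curve's peak to fall before the
  alignment target plus the common-support margin; cohorts with very
  late peaks would shorten the standardised curve's support below the
  scan end, which is an error rather than an extrapolation.
* The vascular correction assumes the vascular regressor is the true
  blood curve; with an input-function proxy the correction degrades
  with input-timing error (see above).
* The slow-boundary lookup covers 60/70/80/90 min only; other durations
  need an explicit boundary.
* Decay correction is assumed already applied (or applied on load) and
  referenced to injection time throughout.
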