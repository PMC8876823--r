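---
title: "Detecting tea adulteration from fluorescence spectra: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tea adulteration from fluorescence spectra: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tieguanyin is a premium oolong tea that is routinely adulterated with
Benshan, a visually near-identical but cheaper cultivar. Fluorescence
hyperspectral imaging offers a fast, non-destructive screen: under
narrow-band excitation, the leaf emits a chlorophyll-dominated spectrum
over 475–1000 nm, and small compositional differences between cultivars
shift the emission shape slightly. `fluortea` implements the full
chemometric workflow for two discriminant tasks on such spectra:

* **2-class** — is a sample pure Tieguanyin (mass fraction of adulterant
  0) or adulterated (10–50 %)?
* **6-class** — which of the six adulteration degrees
  {0, 10, 20, 30, 40, 50 %} does a sample carry?

The workflow is: ROI mean-spectrum extraction → row-wise pretreatment
(SNV, MSC, or 7-point Savitzky–Golay smoothing) → PLS-based
characteristic-wavelength selection (SPA, CARS, random frog, or UVE) →
polynomial-kernel SVM → confusion-matrix metrics, all evaluated on a
stratified 2:1 calibration/prediction split.

## The data model

A `spectrum_set` holds an `n × p` intensity matrix on a shared
`wavelength_grid`, plus per-sample label, adulterant mass fraction and id.
The grid defaults to 104 equally spaced channels from 475 to 1000 nm; the
instrument's true channel spacing is unpublished, so equal spacing is an
explicit assumption, isolated in `default_grid()`. Labels and fractions
are locked together (`label = 10 × fraction`), mirroring the mixing
design, and validation rejects any set violating that map. Raw
intensities must be finite and non-negative; pretreated spectra may be
negative and carry a `preprocessed` flag.

An ENVI-format cube reader (`read_envi`, BSQ/BIL/BIP) and
`roi_mean_spectrum` cover the imaging front end: one rectangular ROI is
reduced to its arithmetic mean spectrum per channel, which is the sample's
spectrum. ROI bounds are 0-based and half-open — composable and
unambiguous.

## What the synthetic generator emulates — and what it does not

Real measurements of the original design are not redistributable, so the
package carries a generator (`default_config()`, `simulate_set()`) whose
defaults *are* the study conditions: six fractions 0–0.5 in 0.1 steps, 48
samples each, 288 in total.

Each endmember (pure Tieguanyin, pure Benshan) is a non-negative baseline
plus Gaussian peaks. The default shapes encode the landmarks of
chlorophyll fluorescence in leaf tissue: a low, broad green-region bump
(amplitude 0.22–0.25 around 590 nm — catechin/theaflavin region), a
reabsorption trough just short of the red emission band (the local
minimum falls at the channel near 674 nm; with a strictly non-negative
Gaussian-sum parameterization the trough cannot be placed exactly at
680 nm, because it arises as the gap between bump and peak rather than
from an explicit absorption dip), and the bimodal emission maxima at the
channels nearest 690 and 735 nm. The two endmembers differ only in small
amplitude/width shifts, so all pairwise correlations between noiseless
class means exceed 0.99 — classes that, like the real cultivars, cannot
be told apart by eye. The endmember contrast is a free parameter: it was
fixed once so that the qualitative behaviour of the real study is
reproduced (2-class nearly saturated, 6-class not), and it makes no claim
about tea chemistry.

A blend with adulterant fraction *f* is the linear mixture
`(1−f)·pure + f·adulterant` — the standard first-order model for a
physical blend of leaf particles. Because the mixture is linear and the
fractions equally spaced, adjacent class means are equidistant, so task
difficulty is governed entirely by the noise model. The observed spectrum
adds the four artefacts the pretreatments are designed to remove, each in
the intensity units of the endmembers (main peak amplitude ≈ 1):

| parameter | default | artefact |
|---|---|---|
| `mult_scale_sd` | 0.01 | per-sample multiplicative gain ~ N(1, ·), particle-size scatter |
| `offset_sd` | 0.003 | per-sample additive baseline shift |
| `baseline_slope_sd` | 5e-6 per nm | per-sample linear drift (tilt) |
| `additive_sd` | 0.003 | i.i.d. channel noise |

Negative values are clipped to zero (fluorescence is physically
non-negative). One RNG stream per `simulate_set` call is consumed in a
fixed documented order (per sample: gain, offset, slope, channel-noise
vector), so output is bitwise reproducible under refactoring.

The generator does **not** emulate radiometric physics (quantum yield,
reabsorption, instrument line shape), spatial image structure, or
non-Gaussian artefact distributions. Passing tests therefore demonstrate
that the pipeline's algorithms behave correctly under the stated
statistical structure — not that any accuracy number transfers to real
tea.

## Pretreatments

All three act row-wise and preserve the grid:

* **SNV** — subtract the row mean, divide by the row standard deviation.
  The *sample* sd (denominator n−1) is used — the dominant chemometrics
  convention; switching to 1/n would be a one-line change. A
  zero-variance row is a degenerate-spectrum error naming the sample.
* **MSC** — ordinary least squares of each row on a reference spectrum,
  then inversion of the fitted gain and offset. Inside the pipeline the
  reference is always the **calibration-partition mean**, applied to both
  partitions, so no information flows from prediction to calibration.
* **SG** — Savitzky–Golay smoothing, default 7-point window and
  polynomial order 2 (the classical smoothing choice; the order is not
  fixed by the original description and is exposed as configuration).
  Edges use the polynomial fitted to the first/last full window,
  evaluated at the edge positions, so the 104-channel grid is never
  shortened. The backend is `signal::sgolayfilt`, whose transient
  handling implements exactly this policy; tests verify every channel
  against an independent per-window least-squares oracle.

The four options (RAW/SNV/MSC/SG) are treated as mutually exclusive
alternatives, matching the structure of the model-comparison tables the
workflow produces.

## The PLS engine

Every selector ranks channels with PLS1 regression coefficients and
judges subsets by RMSECV, so both live in one module.

* **Response coding.** The discriminant task is folded into a single
  ordinal response: 0/1 for the 2-class task, the class label 0–5
  (equivalently fraction × 10) for the 6-class task. The labels are
  ordered and physically meaningful as adulteration degree, which makes a
  single response defensible; one-hot PLS2 would be the alternative and
  is out of scope.
* **Fitting.** NIPALS for a univariate response (non-iterative per
  component). Columns are mean-centred and unit-variance scaled inside
  the fit, which puts coefficient magnitudes on the comparable footing
  that CARS/UVE ranking requires; zero-variance columns get their scale
  clamped to 1 and receive zero weight. Component extraction stops early
  when the residual covariance vanishes, so degenerate (e.g. noiseless,
  rank-deficient) designs are handled without error.
* **Cross-validation.** Default 5-fold with a seeded shuffle; leave-one-out
  for UVE (its classical formulation). The fold shuffle runs in a local
  RNG scope, so calling RMSECV inside a stochastic selector never
  perturbs the selector's own stream. The component count, when not
  given, is the smallest within 2 % of the RMSECV minimum over 1–10 —
  the usual parsimony rule; the original study reports neither latent
  variable counts nor CV schemes, so these are declared defaults,
  surfaced in configuration.

## The four wavelength selectors

All selectors return sorted unique channel indices with method-specific
diagnostics, are deterministic given `rng_seed`, and break all ties
toward the lowest channel index (deterministic and testable).

**SPA** builds, from every possible starting channel, a forward chain
that repeatedly admits the unselected channel with the largest norm after
orthogonal projection away from the selected span — minimizing
collinearity. Chain prefixes are scored by the RMSECV of a plain
multiple-linear-regression model (the original formulation's evaluation
model, not PLS), and the best prefix over all starts wins. Exactly
collinear duplicates have zero residual norm and can never enter a chain.
Default chain bound: 25 of 104 channels.

**CARS** runs N = 50 Monte Carlo iterations (the canonical published
default, with 80 % row sampling). Iteration *i* keeps the
`round(p·r_i)` channels of largest |PLS coefficient|, where
`r_i = a·e^(−k·i)` is the exponentially decreasing schedule pinned by
`r_1 = 1` and `r_N = 2/p`, floored at 2 channels. The subsequent
adaptive reweighted draw is realized as coefficient-weighted sampling
*without* replacement at preserved count — which leaves the retained set
unchanged as a set (the draw still consumes the RNG stream). This
realization is chosen deliberately: it keeps the retained-count trace in
exact agreement with the schedule, which the tests assert, at the cost of
making the competitive step fully deterministic given the row subsample.
The winning subset is the one with minimal full-calibration RMSECV.

**Random frog** walks over channel subsets: a proposal resizes the
current subset to `q* ~ round(N(|V|, 0.3·|V|))` (clamped to [1, p]),
adding uniformly random channels or dropping the weakest-coefficient
ones; it is accepted when RMSECV does not worsen, and otherwise with
probability `0.1·RMSECV(V)/RMSECV(V*)`. A channel's score is its
occupancy fraction across iterations (the subset standing at the start of
each iteration is counted, so the initial subset contributes); channels
at probability ≥ 0.25 are selected, with a top-2 fallback. The proposal
spread (0.3) and acceptance factor (0.1) follow the spirit of the
method's original publication; all are configuration. Because channels
outside the current subset re-enter only through uniform random
additions, mixing time grows with p: the grid default of 500 iterations
is adequate for classification use on 104 channels, while exact support
recovery in the package's planted-signal tests uses 2000 (the original
formulation runs ~10⁴).

**UVE** appends p artificial noise channels (uniform on [0, 1], scaled to
1e-10 of the data's magnitude) and fits one PLS model per leave-one-out
fold on the augmented matrix. Each column's reliability is
`c_j = mean(b_j)/sd(b_j)` across folds; real channels survive when
`|c_j|` exceeds the largest noise-channel `|c|` (times a multiplier,
default 1). These fits deliberately run **without** column autoscaling:
rescaling to unit variance would re-inflate the noise block and defeat
its purpose of being uninformative by construction. A coefficient that is
constant across folds gets reliability ±∞ with a warning; an empty
selection degrades, with a warning, to the single most reliable channel.

Selected channel counts are never forced toward any external reference;
they emerge from the data, and the configuration exposes the bounds and
thresholds for reproduction attempts.

## Classification and evaluation

The split is stratified 2:1 per class (48 → 32/16, 288 → 192/96),
seeded and reproducible. The classifier is a polynomial-kernel SVM
(`(γ·x·z + coef0)^degree`), defaults degree 3, coef0 1, C 1,
`γ = 1/(p'·var)` on features standardized by calibration statistics
(poly kernels are scale-sensitive), one-vs-one multiclass coupling —
standard settings, all exposed, since the original description fixes only
the kernel family.

Metrics follow the counting definitions: with the pure class positive,
sensitivity = TP/(TP+FN) (discrimination of pure tea), specificity =
TN/(TN+FP) (of adulterated tea), overall accuracy = (TP+TN)/n; in the
6-class task, class accuracy = per-class correct fraction and overall
accuracy = confusion-matrix trace over total. `elapsed_seconds` covers
model fit plus the prediction pass only (the boundary of "model time" is
otherwise ambiguous); it is reported but never asserted, being
hardware-dependent.

A PCA diagnostic (mean-centred, top three components with explained
variance shares) provides the customary unsupervised look at class
structure before modelling.

## The grid runner and its determinism contract

`run_grid` executes every pretreatment × selector × task combination on
one shared split: preprocess (statistics from calibration only) → select
on calibration → train on calibration → evaluate both partitions. Each
combination's seed is derived by hashing the combination name into the
global seed, so results do not shift when the grid is reordered or
subset. A failing combination is caught, flagged, and isolated. The
determinism contract is: two runs from one global seed agree exactly on
every scientific quantity; wall-clock timing is excluded
(`report_table(include_time = FALSE)` renders the byte-identical form).
Report tables round percentages to two decimals, half-to-even.

## Numerical choices and degenerate inputs

* Zero-variance columns: scale clamped to 1 inside PLS, sd clamped to 1
  in SVM standardization — both leave such channels inert.
* RMSECV requires every training fold to hold at least
  `n_components + 1` samples; violations are configuration errors, not
  silent degradations.
* Clipping at zero happens after noise addition in the generator.
* Ties (projection norms, |coefficients|, occupancy probabilities) break
  to the lowest channel index everywhere.
* Intensity tables serialize at 17 significant digits, making the
  read/write round trip bit-exact.

## Problem sizes used by the test suite

The suite exercises the full 288-sample design end-to-end: the noiseless
separability check runs all 20 grid combinations at package defaults;
determinism is checked on the full grid with reduced iteration counts
(CARS 15, frog 60, SPA bound 5), which probe the same code paths at lower
cost; planted-signal recovery uses the 104-channel, 150-sample design
with three informative channels over 20 seeds. These sizes are the
package's own verification choices.

## Known limitations

* Synthetic spectra are structurally faithful but radiometrically naive;
  no claim about absolute accuracies on real tea follows from them.
* The single-ordinal-response coding for selector PLS is a modelling
  choice; PLS2/one-hot coding might rank channels differently.
* MSC assumes the affine scatter model; spectra that violate it
  (wavelength-dependent scatter) are only approximately corrected.
* The frog walk's occupancy probabilities depend on run length; short
  runs under-disperse and should be interpreted as rankings, not
  calibrated probabilities.
* Timing numbers are environment-specific and excluded from every
  contract.
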