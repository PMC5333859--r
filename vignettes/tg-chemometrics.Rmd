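---
title: "Estimating biomass composition from thermogravimetric curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biomass composition from thermogravimetric curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgchemo)
```

## The problem

Thermogravimetric analysis (TGA) records the mass of a small biomass sample
while it is heated under a controlled program and atmosphere. Because the
major constituents of lignocellulose devolatilize over characteristic
temperature windows — hemicellulose roughly 150–360 °C, cellulose 250–440 °C,
lignin slowly over a very broad range up to 900 °C — the mass-loss curve
encodes the sample's chemical composition, and the split of the dry mass into
what leaves under nitrogen (volatile matter), what burns when air is admitted
(fixed carbon) and what remains (ash) is exactly the proximate analysis of
the fuel.

`tgchemo` implements and compares the two standard routes from a TG curve to
composition:

1. **Kinetic deconvolution**: read the remaining mass at a handful of fixed
   boundary temperatures and attribute the losses between boundaries to
   individual constituents.
2. **Chemometric calibration**: treat the whole normalized curve as a
   high-dimensional predictor vector and regress each measured property on it
   with latent-variable methods (PCR and PLS), validated by leave-one-out
   cross-validation.

Because the package is developed and tested against simulated data, it also
ships a pseudo-component thermogram generator with known ground truth.

## Heating programs

Two programs are built in, mirroring standard practice for softwood biomass:

* `program_proximate()`: 30→105 °C at 20 °C/min, 5 min hold at 105 °C,
  105→800 °C at 50 °C/min, 7 min isothermal at 800 °C under nitrogen, then
  10 min at 800 °C under air. The air stage oxidizes the char so ash can be
  read off the final residue.
* `program_pyrolysis()`: a single 30→800 °C ramp at 20 °C/min under nitrogen,
  as used in kinetic studies of chemical composition.

Both take roughly 38–40 minutes. All downstream analysis works on curves
**normalized to dry mass**: the portion of the run before the *dry point*
(the end of the 105 °C hold, or the first crossing of 105 °C for programs
without a hold) is discarded and mass is rescaled so the dry-point value is
exactly 100. This removes moisture differences between runs; the generator's
moisture parameter provably does not affect a normalized curve.

## The synthetic-data generator

`generator_config()` defaults define the study conditions:

* **Sampling frame**: 4 biomass groups (whole tree, wood and bark, slash,
  clean wood) × 10 samples = 40 samples.
* **Composition distributions**: per-group means and SDs for lignin,
  cellulose, hemicellulose and ash as reported for loblolly-pine fractions
  (e.g. clean wood: lignin 33.5 (1.6), cellulose 42.7 (2.4), ash 0.4 (0.1) %
  dry mass). Extractive means (whole 4 %, wood & bark 2 %, slash 10 %, wood
  3 %) come from the same material descriptions; their SDs are not reported
  and were fixed once at roughly 25 % of the mean. Constituents are drawn
  from truncated-at-zero normals and the organics rescaled so constituents
  plus ash close at exactly 100. Note that this closure slightly compresses
  constituent SDs (by ~13 % for wood lignin), which the tests account for.
* **Degradation kernels**: each organic constituent survives heating along a
  logistic curve `S(T) = 1 / (1 + exp((T - peak) / (width / 6)))`, affinely
  renormalized to equal exactly 1 at the dry point and 0 at the program's top
  temperature. Defaults: extractives peak 220 °C, hemicellulose 300 °C,
  cellulose 355 °C (the maximum mass-loss temperature of pure cellulose),
  lignin 400 °C with width 500 °C so its decay is slow and broad. Char
  fractions (hemicellulose 0.15, cellulose 0.06, extractives 0, lignin 0.45)
  are generator conventions chosen so lignin dominates fixed carbon; the
  hemicellulose and cellulose kernels deliberately overlap over 250–360 °C,
  which is what biases the kinetic boundary method.
* **Volatile matter / fixed carbon truth** are derived from the char
  fractions (`VM = Σ w_c (1 - char_c)`, `FC = 100 - VM - ash`), so the
  proximate identities hold exactly on noise-free curves: the residue after
  the air stage equals ash to machine precision and the nitrogen-stage loss
  equals volatile matter.
* **Noise**: i.i.d. Gaussian on each recorded mass point, SD 0.5 % of dry
  mass (the low end of reported 0.5–1.3 % run-to-run TGA variation), clipped
  at zero. Real TGA errors also contain correlated baseline drift, buoyancy
  effects and sample-packing effects that this model omits — so a model that
  performs well here is shown to be *correct*, not guaranteed to reach the
  same accuracy on instrument data. In particular, real reference values come
  from independent wet chemistry with its own error, which is why the
  cross-validated R² values on synthetic data (≈0.99 for volatile matter) are
  far higher than one should expect in the laboratory.
* The recording grid (0.05 min default) always includes the program segment
  boundaries so the dry point and stage ends are sampled exactly.

Every draw is controlled by the config seed; `generate_dataset()` is
bit-reproducible.

## Kinetic deconvolution

Three regimes are implemented over normalized curves:

* **KIN1**: masses A, B, C, D after 130, 250, 350, 500 °C;
  hemicellulose = (B−C)/A·100, cellulose = (C−D)/A·100, lignin = D/A·100.
* **KIN2**: masses A, B, C after 180, 360, 440 °C; hemicellulose is the loss
  180–360 °C, cellulose the loss 360–440 °C, lignin the mass after 440 °C
  (all relative to A). The regime is deliberately three-boundary: a fourth
  boundary equal to the third would make the cellulose term identically zero.
* **KIN3** (proximate): A is the dry mass (100), B the mass at the end of the
  nitrogen isothermal hold, C the final residue after oxidation; volatile
  matter = (A−B)/A·100, ash = C/A·100 and fixed carbon by difference, so the
  triple always sums to exactly 100.

Boundary masses are linear interpolations on the heating ramp; temperatures
revisited during isothermal holds resolve to the first crossing, which makes
the lookup deterministic and grid-independent. KIN1/KIN2 are applied to the
nitrogen-only program by default (boundary temperatures are configurable).

Because the hemicellulose and cellulose windows overlap, the boundary method
misattributes the shared losses — its hemicellulose estimates are provably
biased on the synthetic data — and, since each boundary mass is a single
noisy point, its estimates carry the full pointwise noise. Kinetic estimates
are evaluated by the simple linear recalibration `measured = a + b·estimate`
with leave-one-out refits, using the same metric definitions as the
chemometric models.

## Chemometric calibration

`fit_pcr()` and `fit_pls()` are authored from first principles:

* **PCR**: mean-center the columns of X (no unit-variance scaling — all
  features are percent mass, and scaling would inflate noise in flat curve
  regions), take the leading right singular vectors of the centered matrix as
  loadings (eigenvectors of the covariance), project to scores, regress the
  centered response on the first k scores by least squares, and fold the
  coefficients back to feature space.
* **PLS (NIPALS, single response)**: per factor the weight vector is the
  normalized covariance `X'y`, the score is `Xw`, X- and y-loadings come from
  regressing X and y on the score, and X is deflated; coefficients compose
  across factors as `W (P'W)⁻¹ q`.
* Each loading/weight is sign-fixed so its largest-magnitude element is
  positive, making results deterministic across runs. At full rank both
  methods reproduce the ordinary least-squares solution, which the tests
  verify against `lm()`.

**Validation**: `loo_cross_validate()` refits inside every fold (including
re-centering) for factor counts 0..k_max (0 is the mean-only model) and
tabulates PRESS. `select_factors()` then applies a randomized paired test on
the squared held-out residuals of each smaller candidate against the
PRESS-minimizing count (sign-flip null, two-sided, 2000 draws by default,
seeded): the chosen count is the smallest one whose cross-validated error is
statistically indistinguishable (p > 0.1) from the minimum. This mirrors the
parsimony rule used by SAS PROC PLS's CVTEST.

**Metrics** (`compute_metrics()`): SECV = √(PRESS/n);
SEC = √(RSS/(n−k−1)); RPD = SD(reference)/SECV; R² is the squared Pearson
correlation between measured values and held-out predictions, floored at
zero when the correlation is negative — leave-one-out predictions of an
uninformative model are *anti*-correlated with the held-out values (exactly
−1 for the mean-only model), and that artifact must not be reported as
skill. `1 − PRESS/SST` is carried along as the secondary `r2_press`
diagnostic. An SECV of zero flags RPD as undefined (reported `Inf` with a
warning).

**Interpretation**: `coefficient_profile()` aligns the feature-space
coefficients with the time/temperature grid and `profile_peak()` locates the
dominant ramp-temperature contribution. Profiles are best read from
*low-order* PCR fits (3 components): on near-noiseless synthetic data the
parsimony rule legitimately selects 4–7 factors, but the extra factors chase
sample-specific noise directions and wash out the shared structure between
related properties. At 3 components the cellulose profile peaks inside the
cellulose window and the fixed-carbon and lignin profiles are nearly
collinear (r > 0.99), reflecting that lignin's char yield is the dominant
source of fixed carbon in the generator.

## The pipeline

`run_pipeline()` chains the stages deterministically from one seed: draw the
40 compositions, simulate each sample under both heating programs (the
proximate program feeds the chemometric matrix and KIN3; the nitrogen-only
program feeds KIN1/KIN2), normalize, build the 500-point feature matrix,
calibrate PLS and PCR for every requested response, evaluate the kinetic
regimes, and emit a metrics table plus SECV deltas (chemometric − kinetic).
Chemical responses are paired with KIN1/KIN2 and proximate responses with
KIN3; hemicellulose and sugar responses have chemometric models only. With an
`output_dir` all tables, models (JSON) and thermograms (CSV) are written;
identical configs produce byte-identical files.

Problem sizes used throughout the tests — 40 samples, 500 grid points, k_max
10, 2000 randomizations, with smaller variants (12 samples, 150 points) for
unit tests — keep a full pipeline run in single-digit seconds on one core
while leaving the 105–800 °C ramp resolved at ~1.4 °C.

## Numerical choices and degenerate inputs

* PCA is computed by thin SVD of the centered matrix rather than an
  eigendecomposition of the p×p covariance: with n ≪ p (40 × 500) this is
  both faster and better conditioned; rank is judged at `max(d)·1e-10`.
* Requests for more factors than the fold or matrix rank raise errors rather
  than silently truncating; zero-variance responses, zero-variance kinetic
  regressors, dry mass of zero, and missing kernels are all explicit errors.
* If factor selection lands on 0 (no usable signal), metrics are reported at
  0 factors while the stored model is fitted with 1 factor, since a latent
  model with no factors has no interpretable loadings.
* The sugar reference columns are fixed stoichiometric shares of
  hemicellulose and cellulose (softwood galactoglucomannan plus arabinoxylan
  ratios) with a small independent wet-chemistry-style error; they are
  convenience responses for exercising the calibration machinery, not a
  carbohydrate model.

## Known limitations

* The generator's pseudo-components decay independently; real constituents
  interact during pyrolysis, and ash catalysis shifts peaks.
* i.i.d. pointwise noise underestimates the difficulty of ash prediction on
  real instruments, where the incombustible fraction barely imprints on the
  organically-dominated curve; ash is nonetheless the worst-recovered
  property here because its between-sample variance is small relative to the
  noise floor.
* Calibrations are specific to the biomass types and heating programs they
  were built on; models fitted on these four softwood fractions will not
  transfer to other feedstocks without recalibration.
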