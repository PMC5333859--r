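# tgchemo

Chemometric and kinetic compositional analysis of thermogravimetric (TG)
data for lignocellulosic biomass.

A thermogravimetric analyzer records a sample's mass while it is heated
under a controlled program; for forest biomass the resulting mass-loss curve
encodes both the chemical composition (hemicellulose, cellulose, lignin) and
the proximate composition (volatile matter, fixed carbon, ash). `tgchemo`
implements the two classical routes from curve to composition and the
machinery to compare them on a common dataset:

* **Kinetic deconvolution** — read the normalized mass at fixed boundary
  temperatures and attribute the inter-boundary losses to constituents.
  Regime KIN1 uses boundaries 130/250/350/500 °C
  (hemicellulose = (B−C)/A·100, cellulose = (C−D)/A·100, lignin = D/A·100),
  KIN2 uses 180/360/440 °C, and KIN3 splits the dry mass into volatile
  matter = (A−B)/A·100 (loss over the nitrogen stage), ash = C/A·100 (residue
  after oxidation in air) and fixed carbon by difference.
* **Chemometric calibration** — regress each measured property *y* on the
  full normalized curve **X** with principal component regression (PCR:
  scores Zᵢ = Σⱼ eᵢⱼXⱼ from the eigenvectors of cov(X), then least squares on
  the leading scores) or partial least squares (NIPALS, weights ∝ X'y so the
  factor scores maximize covariance with the response). Models are validated
  by leave-one-out cross-validation; the factor count is the smallest one
  whose PRESS is statistically indistinguishable (randomized paired test,
  p > 0.1) from the minimum; performance is reported as SECV = √(PRESS/n),
  R² (measured vs held-out predictions), and RPD = SD(y)/SECV.
* **A pseudo-component thermogram simulator** — 40 samples in 4 biomass
  groups (whole tree, wood & bark, slash, clean wood) with realistic
  composition distributions, logistic devolatilization kernels per
  constituent, char burn-off under air, and seeded pointwise noise — so every
  estimate can be scored against known truth.

See `vignettes/tg-chemometrics.Rmd` for the models, parameter meanings,
defaults, and design decisions.

## Worked example

```r
library(tgchemo)

cfg <- pipeline_config(generator = generator_config(seed = 1), seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
subset(as.data.frame(res$metrics),
       property %in% c("lignin", "volatile_matter"))
```

```
        property method    SEC   SECV    R2   RPD r2_press n_factors  n
          lignin    PLS 0.1188 0.1869 0.998 22.36    0.998         4 40
          lignin    PCR 0.1395 0.1828 0.998 22.85    0.998         5 40
 volatile_matter    PLS 0.0203 0.0533 0.999 38.39    0.999         5 40
 volatile_matter    PCR 0.0327 0.0554 0.999 36.97    0.999         8 40
          lignin   KIN1 2.1271 2.1693 0.724  1.93    0.723         1 40
          lignin   KIN2 1.6506 1.6871 0.833  2.48    0.833         1 40
 volatile_matter   KIN3 0.4540 0.4624 0.948  4.43    0.948         1 40
```

Reading the table: on the default 40-sample synthetic dataset the latent
variable models predict lignin with a cross-validation error (SECV) of
~0.19 % dry mass versus 1.7–2.2 % for the boundary-temperature methods, and
volatile matter at ~0.05 % versus 0.46 % — the chemometric models beat the
kinetic ones for every property, because they average information over the
whole 500-point curve while each kinetic estimate rests on a handful of
single noisy mass readings and misattributes the overlapping
hemicellulose/cellulose losses. An RPD above ~1.5 is conventionally usable
for screening. The factor-selection trace for volatile matter shows the
parsimony rule at work: PRESS is minimized at 9 latent variables, but 5 are
statistically indistinguishable and are chosen:

```r
res$calibrations$volatile_matter$PLS$cv$press_by_factors[1:6]
#>       0       1       2       3       4       5
#> 171.830   1.227   0.677   0.355   0.147   0.114
```

A full run from the shell:

```sh
Rscript inst/scripts/tg-pipeline.R --stage run --seed 1 --out tgchemo_out
```

writes the thermograms, truth table, fitted models (JSON), metrics table and
the comparison report under `tgchemo_out/`.

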