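# soilcos

Synchronous two-dimensional correlation spectroscopy (2D-COS) and
band-selection PLSR for predicting soil organic matter (SOM) from moist-soil
vis-NIR spectra.

## The problem

Soil organic matter is routinely estimated from visible/near-infrared
(400–2450 nm) absorbance spectra, but the SOM absorption features are weak
and sit underneath two dominant water bands (near 1410 and 1906 nm when dry,
red-shifting towards 1453 and 1928 nm as gravimetric moisture rises to 17%
w/w). In moist field samples the moisture signal overwhelms the SOM signal
and degrades regression models. `soilcos` implements a two-perturbation
2D-COS workflow that separates the two effects, identifies which wavebands
respond to moisture and which to SOM, and uses that information to select
spectral bands for a SIMPLS partial least squares regression (PLSR) of SOM
content.

## The method

For a series of spectra \(y(\nu, p)\) measured under a perturbation \(p\)
(here: moisture % w/w, or SOM % w/w), the *dynamic spectra* are the
deviations from the perturbation-averaged reference,
\(\tilde y(\nu, p) = y(\nu, p) - \bar y(\nu)\). The *synchronous correlation
map* is the band-to-band sample covariance across the series,

\[ X(\nu_1, \nu_2) = \frac{1}{m-1} \sum_{j=1}^{m}
   \tilde y(\nu_1, p_j)\, \tilde y(\nu_2, p_j). \]

Its diagonal \(X(\nu,\nu)\) — the correlation strength — is the variance of
intensity at each band under the perturbation; local maxima of the diagonal
are *auto-peaks* marking perturbation-sensitive bands, and off-diagonal
*cross-peaks* carry a sign telling whether two bands co-vary or counter-vary.
Holding SOM fixed and perturbing moisture locates the moisture bands; holding
moisture fixed and perturbing SOM locates the SOM bands (597, 1646, 2138 nm,
quenched once moisture reaches about 10%).

Detected moisture bands (±51 nm windows around 1447, 1934 and 2210 nm) are
then excluded from the predictor set, and SOM is regressed on the retained
bands with SIMPLS PLSR under a nested five-fold cross-validation. Models are
assessed by R²c/R²cv/R²p, RMSEC/RMSECV/RMSEP (calibration RMSE uses the
`Ic − f − 1` degrees-of-freedom denominator, with `f` latent variables) and
RPD = SD/RMSEP with the usual quality classes (≥ 2.5 excellent, 2.0–2.5 very
good, 1.8–2.0 good, 1.4–1.8 fair, < 1.4 unacceptable). Four preset band-set
experiments are provided: **A** all 2051 bands (400–2450 nm), **B** minus
the three moisture windows (1748 bands), **C** additionally minus the noisy
400–500 nm region (1648 bands), **D** the SOM bands only (459 bands).

Because the original 50-sample loam field spectra were never deposited, the
package ships a synthetic generator that reproduces the statistical
structure of moist-soil spectra — water peaks growing and red-shifting with
moisture, weak SOM features quenched by moisture, baseline darkening,
elevated blue-region noise — so every stage is testable end to end.

## Worked example

```r
library(soilcos)

cfg   <- default_synthetic_config(seed = 1, som_levels = som_study_levels(50))
study <- generate_study(cfg)   # 50 SOM levels x 5 moisture dosings
study
#> <spectrum_set> 250 sample(s) x 2051 band(s), 400-2450 nm

# SOM as the perturbation, moisture held fixed per group
tab <- correlation_strength_table(study, "som", group_by = "moisture")
subset(tab, group_label %in% c(0, 17))
#>  group_label wavelength_nm     strength
#>            0           404 0.0001614090
#>            0           425 0.0001840601
#>            0           459 0.0001502390
#>            0           496 0.0001508063
#>            0           599 0.0006376362
#>            0          1649 0.0002353533
#>            0          2138 0.0001205602
#>           17           487 0.0001615922
#>           17          1452 0.0010543213
#>           17          1929 0.0023736908

m <- run_experiment(study, experiment_bandset("C"), seed = 1)
m
#> <model_metrics> [C] bands=1648 R2c=0.896 RMSEC=0.363 R2cv=0.817
#>   RMSECV=0.510 R2p=0.815 RMSEP=0.515 RPD=2.33 (very_good)
```

Reading the output: in the oven-dry group the SOM auto-peaks surface at
599, 1649 and 2138 nm (within the ±5 nm waveband uncertainty of the planted
597/1646/2138 nm features), alongside weak noise maxima in the 400–500 nm
region; at 17% moisture the SOM peaks are quenched and only the red-shifted
water bands (1452, 1929 nm) remain. The experiment-C regression predicts SOM
with a pooled out-of-fold R²p of 0.82 and an RPD of 2.33 ("very good") on
this synthetic study.

The full pipeline (simulate → trim → 2D-COS tables under both perturbations
→ band sets → experiments A–D → report) is one call:

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

or, from a shell, `Rscript inst/scripts/run_pipeline.R --synthetic
--out-dir run1 --seed 1`.

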