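# wetspec

PLS-1 calibration of handheld near-infrared (NIR) spectra for **undried
forage** quality estimation.

Forage quality — crude protein (CP), neutral and acid detergent fiber
(aNDF, ADF), lignin (ADL) and digestibility (IVTD, NDFD), all in %DM —
can in principle be read off a NIR spectrum in seconds with a handheld
instrument, directly on wet haylage at the silage bunker. Two things make
that hard: liquid water's O–H absorption bands (1460 nm, and the very large
band at 1904 nm) dominate the spectrum of a sample that is half water, and
unground forage is heterogeneous at the scale of the illumination spot, so
the scanning pattern (static spot, hand-moved, rotating turntable) changes
how representative each scan is.

`wetspec` implements the complete chemometric workflow for this setting:

* **Spectral I/O and harmonization** — wide-CSV reflectance spectra with
  per-scan metadata; piecewise-linear resampling to a common grid
  (default 1454–2446 nm, 4 nm); `log10(1/R)` absorbance; replicate
  averaging.
* **Savitzky–Golay derivatives** — general least-squares implementation
  supporting *even* window lengths (default window 4, polynomial order 3,
  first derivative, per-nm scaling), with polynomial refitting at the edges.
* **NIPALS PLS-1** — written from scratch, with a fixed sign convention,
  per-LV explained variance, loading spectra, coefficient paths and JSON
  model serialization. At full rank it agrees with least squares to
  machine precision (tested against `lm.fit`).
* **Outlier screening** — Q residuals and Hotelling's T² with F-based and
  empirical-quantile 95% limits (Jackson–Mudholkar optional).
* **Evaluation** — bunker-aware 90/10 splitting and group-aware 5-fold CV,
  latent-variable grid search (1–20), RMSE/Bias/SE/SECV/R²/R²CV/RPD/RPD(CV),
  Malley level-of-success and Williams RPD classification tiers.
* **Water-band analysis** — loading spectra annotated against the canonical
  water absorption bands, with per-band loading-mass summaries.
* **A seeded synthetic campaign generator** — 600 samples from 111 farm
  bunkers, five replicate scans, three instrument grids and three scan
  modes by default — so the entire pipeline is testable end to end without
  instrument data.

The model at the core is standard chemometrics: on mean-centred derivative
spectra, NIPALS extracts latent variables `w_a = X'y/||X'y||`,
`t_a = X w_a`, `p_a = X't_a/(t_a't_a)`, `q_a = y't_a/(t_a't_a)` with
deflation, giving the regression vector `b = W(P'W)⁻¹q`. Metrics follow the
NIRS conventions `SE² = n(RMSE² − Bias²)/(n−1)` and `RPD = SD(y)/SE`. The
methods vignette (`vignettes/wetspec-methods.Rmd`) documents every design
decision, the generator's assumptions, and what passing tests do and do not
show about real forage spectra.

## A worked example

```r
library(wetspec)

cfg  <- synthetic_config(seed = 42, n_samples = 300, n_groups = 60)
camp <- make_campaign(cfg, streams = data.frame(
  instrument = c("agrocares", "neospectra"),
  scan_mode  = c("static", "turntable")))

cal <- run_calibrate(camp$spectra, camp$reference,
                     pipeline_config(seed = 7, constituents = c("CP", "aNDF")))
val <- run_validate(cal, camp$spectra, camp$reference)
val
```

```
<validation_result>
best model per constituent:
                stream constituent  n  rmse   bias    se    r2 slope intercept
1 neospectra.turntable        aNDF 35 0.609 -0.096 0.610 0.994 1.012    -0.726
2 neospectra.turntable          CP 35 0.256  0.068 0.251 0.997 0.976     0.495
     rpd lv   success classification
1 13.634  5 Excellent      Excellent
2 18.251  5 Excellent      Excellent
```

Reading the output: `rmse`/`se` are in %DM; `r2` is 1 − SSE/SST on the
held-out bunkers; `rpd` is the reference SD over SE (higher is better);
`lv` is the latent-variable count selected by group-aware cross-validation;
the last two columns are the Malley and Williams tier labels. The turntable
stream wins for both constituents — averaging ten sub-spots per scan
suppresses sample heterogeneity — which is the qualitative behaviour the
package's acceptance tests assert. Synthetic spectra are much cleaner than
real haylage scans, hence the optimistic absolute numbers; see the vignette.

Loading spectra can be inspected against the water bands:

```r
m <- cal$models[["neospectra.turntable"]][["CP"]]
band_loading_summary(loading_spectrum(m, 1)$loading, m$wavelengths)
```

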