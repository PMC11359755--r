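---
title: "Calibrating handheld NIRS for undried forage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating handheld NIRS for undried forage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetspec)
```

## The problem

Handheld near-infrared spectrometers promise on-farm estimation of forage
quality — crude protein (CP), fiber fractions (aNDF, ADF, ADL) and
digestibility measures (IVTD, NDFD) — directly on wet, unprocessed haylage.
Two features make undried material hard. First, liquid water absorbs strongly
in the NIR (O–H bands near 1460 and especially 1904 nm) and dominates the
spectrum of a sample that is half water by mass. Second, unground forage is
heterogeneous at the scale of the instrument's illumination spot, so the way
the sample is presented — a static spot, a hand-moved scan, or a rotating
turntable — changes how representative each spectrum is.

`wetspec` implements the full calibration workflow for this setting, along
with a seeded synthetic-campaign generator so that every stage can be
exercised and tested end to end without access to instrument data.

## The pipeline

For each (instrument, scan mode) stream and each constituent:

1. **Harmonization.** Reflectance spectra are linearly interpolated onto a
   common arithmetic grid, by default 1454–2446 nm at a 4 nm step — the
   intersection of typical handheld ranges at the fixed step. Interpolation
   is piecewise linear: shape-preserving, with no overshoot near the sharp
   water band shoulders at the range limits. No extrapolation is ever
   performed; a requested range outside the source span is an error.
2. **Absorbance.** $A = \log_{10}(1/R)$.
3. **Derivative.** A Savitzky–Golay first derivative with window 4 and
   polynomial order 3 (see below).
4. **Replicate handling.** The replicate scans of a sample are averaged
   before modelling (default). Modelling replicates individually is
   supported (`keep_all`) but inflates the apparent sample size with
   pseudo-replicates, so the mean is the default.
5. **Bunker-aware split.** Whole groups (farm bunkers) are assigned to the
   validation side until it first reaches 10% of samples; with the default
   emulated design (600 samples, 111 bunkers) this yields ~540 calibration
   and ~60 validation samples. No bunker ever appears on both sides.
6. **Outlier screening.** A PLS-1 model (10 latent variables by default) on
   the calibration set yields per-sample Q residuals and Hotelling $T^2$;
   samples exceeding both 95% limits are removed (see below). Validation
   samples are never screened — that would flatter the validation metrics.
7. **Latent-variable selection.** Grid search over 1–20 latent variables
   under group-aware five-fold cross-validation (~432 train / ~108 held-out
   per fold); the count minimizing the pooled CV RMSE is selected, ties
   going to fewer variables. A one-standard-error rule is available.
8. **Reporting.** Calibration metrics (RMSE, Bias, SE, SECV, R², R²CV, RPD,
   RPD(CV), LVs) and validation metrics (plus slope, intercept and the
   Malley / Williams tier labels), with a best-per-constituent summary by
   minimum validation RMSE.

The exported functions `make_campaign()`, `run_calibrate()` and
`run_validate()` — together with the lower-level operations they compose —
are the package interface; configuration is by plain R constructors
(`pipeline_config()`, `synthetic_config()`).

## Savitzky–Golay with an even window

The filter is implemented as general local least squares: a degree-$q$
polynomial is fitted to each window of $w$ equally spaced points and its
$d$-th derivative evaluated at the window's centre index $\lfloor w/2
\rfloor$ (0-based). This supports *even* windows, which common
implementations reject: with $w = 4$, $q = 3$ the fit interpolates the four
points exactly, and the evaluation point is the later of the two central
points, so output stays on the sampling grid. Users preferring the odd
convention can set `odd_window = TRUE`, which maps 4 to 5.

Derivatives are scaled per nm (divided by `step^deriv`) so loading spectra
are comparable across instruments with different native steps. Edge points
are computed by refitting the polynomial to the nearest full window and
differentiating it at the actual wavelength — not by padding, which would
create reflection artefacts at the 1454/2446 nm water shoulders. The filter
is exact on polynomials up to degree 3 at every point, a property the test
suite asserts to ten significant digits.

## NIPALS PLS-1

For a single response the NIPALS recursion is finite — no inner iteration:

$$w_a = X_a' y_a / \lVert X_a' y_a \rVert,\quad t_a = X_a w_a,\quad
  p_a = X_a' t_a / t_a' t_a,\quad q_a = y_a' t_a / t_a' t_a,$$

followed by deflation $X_{a+1} = X_a - t_a p_a'$, $y_{a+1} = y_a - t_a q_a$,
on mean-centred data. The regression vector is $b = W (P'W)^{-1} q$ with
intercept $b_0 = \bar y - \bar x \cdot b$. Design choices:

* **Centring only** (no autoscaling) by default — standard for derivative
  spectra, where amplitude carries information. `scale = TRUE` enables
  autoscaling.
* **Sign convention.** The NIPALS sign is arbitrary; each $w_a$ is flipped
  so its largest-magnitude element is positive, making loadings reproducible
  bit-for-bit across runs and platforms.
* **Rank tolerance.** $\lVert X_a'y_a\rVert$ below $10^{-12}$ of its initial
  value is treated as rank exhaustion and reported with the step index.
* At full rank the fitted values coincide with the least-squares solution;
  the tests verify this against `lm.fit` on dozens of random problems, and
  against closed-form OLS for a single predictor.

Per-LV explained variance is accumulated during the recursion: the X
fraction of LV $a$ is $\lVert t_a p_a'\rVert_F^2 / \lVert X_1\rVert_F^2$ and
the y fraction is its incremental R². Loading spectra (`loading_spectrum()`)
pair $p_a$ with the wavelength grid for inspection against the water bands.

## Q residuals and Hotelling's T²

With rotation $R = W(P'W)^{-1}$, a centred spectrum $x_0$ has scores $t =
x_0'R$, reconstruction $\hat x_0 = t P'$, $Q = \lVert x_0 - \hat x_0
\rVert^2$, and $T^2 = \sum_a t_a^2 / s_a^2$ with $s_a^2$ the
$(n-1)$-denominator variance of the calibration scores (hence
$\sum_i t_{ia}^2/s_a^2 = n-1$ per LV, an identity the tests assert). The
$T^2$ limit is the classical $\frac{A(n-1)(n+1)}{n(n-A)} F_{1-\alpha}(A,
n-A)$. The Q limit is by default the empirical 95th percentile of the
calibration Q values — distribution-free, robust to the decidedly
non-Gaussian residuals of derivative spectra — with the Jackson–Mudholkar
closed form available for comparison.

Two decisions were genuinely open. The combination rule defaults to
`both_exceed` (a sample must violate both limits), which is conservative and
removes fewer borderline samples; `either_exceeds` is available, and is the
right rule for detecting purely off-subspace artefacts, which by
construction inflate Q but need not move the within-subspace scores at all.
Screening is a single pass — no refit-and-rescreen iteration — because
iterated deletion on derivative spectra tends to chew into the legitimate
tails of a heterogeneous sample population.

## Metrics and classification

For errors $e_i = \hat y_i - y_i$: $\mathrm{bias} = \bar e$,
$\mathrm{RMSE} = \sqrt{\overline{e^2}}$, and the bias-corrected standard
error $\mathrm{SE} = \sqrt{\sum (e_i - \bar e)^2/(n-1)}$, so that
$\mathrm{SE}^2 = n(\mathrm{RMSE}^2 - \mathrm{bias}^2)/(n-1)$ — an identity
that lets reported SE values be checked against reported RMSE and bias,
which both the tests and `scripts/acceptance.R` do. $R^2 = 1 -
\mathrm{SSE}/\mathrm{SST}$ (not squared correlation), consistent with
RMSE-based reporting. $\mathrm{RPD} = \mathrm{SD}(y)/\mathrm{SE}$ with the
$(n-1)$-denominator SD of the evaluated subset; this convention reproduces
the internal consistency of published calibration tables (e.g. SE 2.756
with RPD 2.090 implies a subset SD near 5.76). SECV, R²CV and RPD(CV) apply
the same formulas to held-out predictions *pooled* across folds (pooled, not
fold-averaged — the two differ, and pooled is what is reported). The
regression line is predicted-on-reference ($\hat y = \beta y + c$).

Malley's level-of-success tiers on R² (< 0.80 Not useful; 0.80–0.90
Moderately Successful; 0.90–0.95 Successful; ≥ 0.95 Excellent) and
Williams' RPD tiers (< 2.0 Very poor; 2.0–2.5 Poor; 2.5–3.0 Fair; 3.0–3.5
Good; 3.5–4.0 Very good; ≥ 4.0 Excellent) are implemented as total,
monotone step functions, half-open on the left as listed (the published
tier tables print touching ranges without boundary rules). Published
summaries occasionally drift from their own tier table — an RPD of 3.452
is sometimes labelled "Very good" although it falls in the 3.0–3.5 "Good"
band; `classify_rpd()` follows the table, and returns "Good".

## The synthetic campaign generator

The generator exists so that the whole pipeline is testable with the
statistical structure the analysis assumes. It is **not** a physical model
of diffuse reflectance (no Kubelka–Munk scattering, no temperature-dependent
band shifts).

**Reference chemistry.** Constituent vectors are drawn from a Gaussian
copula: a latent standard multivariate normal with a configurable
correlation matrix (fiber fractions mutually positive, protein and
digestibility negative against fiber) is mapped coordinate-wise through
truncated-normal quantile functions. The latent marginal parameters are
moment-matched so the *truncated* distribution reproduces the configured
mean and SD — naive truncation of an MVN would shrink the SD several
percent and, through the correlations, bias the means of other
constituents. Defaults are the summary statistics of laboratory wet
chemistry for mixed alfalfa–grass haylage (`default_reference_stats()`),
with min/max as hard bounds. Bunker structure enters as a latent random
intercept carrying 30% of the SD, which makes group-wise splitting
consequential and testable. Digestibility is conditionally an affine
function of the other constituents plus independent noise — which is what a
conditional Gaussian is — and gets **no absorption bands** of its own:
digestibility is not a chemical species, its NIR signal is indirect, and
the generator accordingly reproduces the empirical finding that IVTD and
NDFD calibrate much worse than CP or the fiber fractions.

**Spectra.** Absorbance is a sum of Gaussian bands: per-constituent band
profiles (CP near the N–H combination bands at 2055/2180 nm; fiber at
1730/2100/2270–2330 nm; lignin sharing fiber bands at low amplitude) scaled
by concentration, plus the water profile (relative amplitudes 1 : 10 : 25
for very small : large : very large bands; 1.2 absorbance at 1904 nm per
unit moisture fraction) scaled by a fresh-basis moisture fraction drawn
uniformly in 0.45–0.70, typical of haylage and independent of composition.
A per-sample jitter of the water band centres (SD 2 nm) emulates
hydrogen-bonding matrix shifts, so moisture occupies more than one latent
dimension and genuinely interferes with overlapping constituent bands.
Moisture enters additively rather than diluting the dry-matter signal; the
multiplicative coupling of real wet samples is a known limitation, accepted
so that the noise-free generative model is exactly linear and parameter
recovery can be asserted exactly.

**Scan modes and instruments.** A scan averages 1 (static), 5 (moving) or
10 (turntable) sub-spots whose compositions are perturbed with relative SD
τ = 0.08 by default; each sub-spot also gets a random baseline
(offset/slope) and multiplicative scatter. Replicate-to-replicate variance
at a band centre therefore scales as 1/m in the sub-spot count, which is the
mechanism behind the turntable ≥ moving ≥ static performance ordering the
tests assert. Two fixed-grid instruments report 1454–2446 nm at 4 nm with a
delta line-shape; a wide-range instrument reports 1350–2550 nm on a variable
grid (step 2.5–8.8 nm, densest mid-range) convolved with a 16 nm FWHM
Gaussian line-shape, matching the stated resolution of that instrument
class. White noise (SD 0.002 absorbance) is added on the instrument grid
and reflectance is emitted as $R = 10^{-A}$.

**What passing tests do and do not show.** The generator produces data far
cleaner than real haylage spectra — validation R² near 0.99 for CP, versus
~0.89 for real undried forage — because real spectra contain structured
residuals (particle-size scattering, specular artefacts, temperature) that
no Gaussian-band model reproduces. Passing the suite demonstrates the
*correctness of the algorithms* and the *qualitative behaviour* of the
workflow (constituent hierarchy, scan-mode ordering, overfitting signature,
water-band loading structure), not field-level accuracy.

## Numerical and testing choices

* Grid-equality checks use a $10^{-6}$ nm tolerance; grids whose nodes are
  integers within that tolerance are snapped to integers.
* LV selection breaks ties toward fewer variables; rank exhaustion inside a
  CV fold truncates the scan with a recorded warning rather than failing.
* Degenerate inputs fail loudly: zero response variance, non-uniform grids
  passed to the derivative filter, extrapolation requests, confidence levels
  outside (0,1), more latent variables than `min(n-1, p)`.
* The stylized overfitting experiment (three banded constituents, reference
  noise SD 1.5 on CP, instrument noise 0.002) shows the canonical
  RMSE-vs-LV signature: calibration error monotone decreasing, CV error
  minimized at the generating component count and trending up beyond ~10
  LVs. A pooled five-fold CV curve is a stochastic estimate, so the tests
  assert the trend (every post-10 value above the CV minimum, the curve
  ending above its start, increments non-negative within 1% of the level)
  rather than strict per-step monotonicity, which random fold noise breaks
  at the few-tenths-of-a-percent scale. Problem sizes in the suite (600
  samples for shape experiments, 150–300 for pipeline integration) were
  chosen to keep the full suite comfortably fast while leaving the
  qualitative behaviour unambiguous.
* Water-band positive controls are run on absorbance spectra: the loading of
  a moisture-driven response peaks at the 1904 nm band centre on absorbance,
  whereas after a first derivative the extrema sit at the band's inflection
  points (±1 band-width), so centre-locality is only meaningful
  pre-derivative.

## Known limitations

* Additive moisture (no dry-matter dilution or water–matrix band shape
  change beyond centre jitter).
* No SNV/MSC/detrending preprocessing and no wavelength selection — the
  modelled workflow uses none.
* PLS-1 only; no PLS-2, kernel or sparse variants.
* Outlier screening is single-pass by design; y-residual (studentized)
  tests are out of scope.
* The generator's inter-constituent correlations are plausible defaults,
  not estimates from any particular data set; they are fully configurable.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 42, n_samples = 300, n_groups = 60)
camp <- make_campaign(cfg, streams = data.frame(
  instrument = c("agrocares", "neospectra"),
  scan_mode = c("static", "turntable")))
cal <- run_calibrate(camp$spectra, camp$reference,
                     pipeline_config(seed = 7, constituents = c("CP", "aNDF")))
val <- run_validate(cal, camp$spectra, camp$reference)
val$best
```
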