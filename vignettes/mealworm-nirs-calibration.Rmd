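---
title: "NIR calibration of fat and fatty acids in living mealworm larvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIR calibration of fat and fatty acids in living mealworm larvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealwormNIRS)
```

## The problem

Mealworm (*Tenebrio molitor*) larvae are reared commercially as food and
feed, and their fat content and fatty-acid profile respond strongly to the
rearing diet. Wet-chemistry reference methods (Soxhlet extraction, FAME
derivatisation and GC) are destructive and slow. Near-infrared reflectance
spectroscopy offers a non-destructive alternative: absorbance of living
larvae between 1100 and 2100 nm carries overtone and combination bands of
C–H, O–H and N–H bonds, with fat-linked features near 1205, 1727 and
1797 nm and water/protein features near 1454 and 1930 nm.

This package implements the full calibration loop that turns such spectra
plus reference chemistry into predictive models: spectral pretreatment,
PLS1 regression, latent-variable selection by cross-validation, and
evaluation on an independent validation set. Around the core it provides
the bookkeeping that a feeding-trial study needs: fatty-acid class
accounting, growth and feed-conversion metrics, and diet-formulation
arithmetic.

## The calibration model

For a single analyte $y$ (fat in g/100 g fresh weight, or a fatty acid in
% of total fatty acids) and a spectra matrix $X$ ($n$ samples $\times$ $p$
wavelengths), PLS1 builds rank-one components that maximise covariance
with the response. The NIPALS sequence per component $a$ is

$$
w_a = \frac{X_{a-1}^\top y_{a-1}}{\lVert X_{a-1}^\top y_{a-1}\rVert},\quad
t_a = X_{a-1} w_a,\quad
p_a = \frac{X_{a-1}^\top t_a}{t_a^\top t_a},\quad
q_a = \frac{y_{a-1}^\top t_a}{t_a^\top t_a},
$$

followed by deflation $X_a = X_{a-1} - t_a p_a^\top$, $y_a = y_{a-1} - q_a
t_a$. With a univariate response the weight vector is exact in one pass,
so the fit is fully deterministic. The regression vector in original units
is $b = W (P^\top W)^{-1} q$, and `fit_pls1()` stores the cumulative $b$
for every component count so cross-validation can score all model sizes
from a single fit per fold.

Evaluation uses the standard chemometric statistics: RMSEC/RMSEP (root
mean square error on the calibration/validation set),
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, the ratio of performance to
deviation $\mathrm{RPD} = \mathrm{SD}_{\mathrm{val}} / \mathrm{RMSEP}$,
and, for fatty acids, $R^2_F$, the squared Pearson correlation of the
acid's relative concentration with total fat. $R^2_F$ separates
calibrations that merely ride on the broad fat signal from calibrations
that exploit an acid's own absorption features.

Two conventions deserve a note, since published tables rarely state them:

* **RPD uses the validation-set SD** with the $n-1$ denominator. This is
  the only convention under which the identity
  $\mathrm{RPD} \times \mathrm{RMSEP} = \mathrm{SD}$ holds inside every
  row of the bundled performance tables (it does, to the printed
  precision; `verify_reference_tables()` recomputes all sixteen rows).
* **$R^2_P$ is $1-\mathrm{SSE}/\mathrm{SST}$**, not a squared
  correlation. The two differ only by the model's bias term; we fix the
  variance-explained form because it makes $R^2_P$, RMSEP and RPD
  mutually consistent on the same set.

## Pretreatments

`standard_pretreatments()` screens the five treatments routinely compared
for this kind of data — none, MSC, mean centering, first and second
derivative — and `pretreatment_spec()` composes arbitrary step sequences
(e.g. `pretreatment_spec("msc", "detrend")`, applied in the listed order,
MSC first).

* **MSC** regresses each spectrum on the calibration mean spectrum
  ($s \approx a + b\,\bar s$) and returns $(s-a)/b$. The reference is the
  calibration mean (the usual convention); validation spectra are always
  corrected against the *stored* reference. MSC is idempotent on spectra
  that follow its scatter model exactly; on general data a second pass
  re-estimates the reference and is therefore only approximately the
  identity.
* **Detrend** subtracts a per-spectrum least-squares polynomial in
  wavelength, default order 2 (the classic detrend). It is a stateless
  orthogonal projection: exact polynomials map to zero and the transform
  is idempotent and linear.
* **Mean centering** stores calibration column means and subtracts them
  from every set.
* **Derivatives** use Savitzky–Golay local polynomial fits with respect
  to wavelength, default window 11 points and polynomial order 2 (first
  derivative) or 3 (second). The source tables name the derivatives
  without smoothing parameters, so these defaults are stated assumptions
  and both are exposed in the step specification. Units follow the grid:
  a first derivative is absorbance per nm. Edge points are refitted on
  the truncated window rather than extrapolated.

Stateful steps (MSC reference, column means) are estimated from the
calibration set only and replayed on validation/prediction spectra; the
test suite checks that changing the validation data cannot change the
fitted state.

**Centering and PLS interact.** A pipeline containing the `mc` step feeds
centered spectra into a centered PLS; any other pipeline runs PLS on the
raw cross-products, without an intercept. This is what makes "None" and
"MC" genuinely different candidate models in the reports, matching how
chemometrics software treats mean centering as a preprocessing choice
rather than a regression constant.

## Latent-variable selection

`cross_validate()` refits the model from scratch on each training fold and
pools held-out squared errors into RMSECV per component count; the chosen
count minimises RMSECV subject to a cap, with ties resolved toward fewer
components. Defaults: venetian-blind folds with 10 splits (a common
chemometrics default for data without serial structure; contiguous blocks
and leave-one-out are also provided) and a cap of 10 latent variables,
reflecting the usual "fewer than ten factors" modelling rule for this
data. `run_calibration(force_n_lv = 8)` reproduces the fixed-eight-factor
setting used in published fatty-acid models, for users who prefer that
mode; the default is CV selection because the cross-validation statement
is the only stated selection mechanism that is unambiguous.

If deflation exhausts the predictors before the requested number of
components (exactly rank-deficient data), extraction stops and the
remaining components contribute nothing; cross-validation then sees equal
RMSECV beyond the effective rank and the parsimony tie-break still selects
the smallest adequate model.

## Composition, growth and diet arithmetic

Fatty-acid profiles are relative percentages of total fatty acids
(`peak_areas_to_percent()` performs the GC area normalisation), classified
into SFA (C12:0, C14:0, C16:0, C18:0), MUFA (C16:1, C18:1ω9) and PUFA
(C18:2ω6, C18:3ω3) by a data-driven map that can be extended to
longer-chain acids without code change. A not-detected acid contributes
zero. `validate_profile_consistency()` is a QC step for published-table
inputs: it recomputes class sums and surfaces rows that disagree with
their printed totals. On the bundled larval table it flags five sums as
internally inconsistent beyond print rounding (largest: the CF20 SFA sum,
where the listed components add to 37.0 against a printed 40.0); the QC
surfaces these, it does not resolve them.

Growth metrics follow the standard insect feeding-trial formulas: weight
gain per surviving larva (mg), feed conversion ratio
$\mathrm{FCR} = \text{feed consumed}/\text{weight gained}$, conversion
efficiency $\mathrm{ECI} = 100/\mathrm{FCR}$, and specific growth rate
$\mathrm{SGR} = 100\,(\ln w_{\mathrm{end}} - \ln w_{\mathrm{start}})/
\text{days}$ on mean per-larva body weights. Records store group totals
and counts; with equal survivor counts the total-weight ratio equals the
mean-weight ratio, and the stored-count form handles mortality correctly.
Feed consumed is the dry-diet mass balance (offered minus residual minus
frass); the weekly fresh-carrot water source is not counted as feed.

Diet formulation is linear mixing: `mix_nutrients()` computes
fraction-weighted nutrient vectors, `solve_inclusion()` inverts it for a
target value, and `solve_component_values()` recovers the two pure
component values from any two mixtures of the same pair — which is how
the package cross-checks printed inclusion percentages against printed
diet fat contents without knowing the suppliers' ingredient analyses.

## The synthetic data generator

The study's raw spectra are not publicly deposited, so the package ships
a generator that emulates the *statistical structure* the analysis
assumes, making the whole pipeline testable end to end:

* **Reference chemistry** (`generate_reference()`): per feeding group,
  fat is a truncated normal; the fatty-acid profile is Dirichlet-
  distributed around the group's mean profile (bundled composition
  table) and renormalised to 100%, so compositional constraints are
  respected and not-detected acids stay exactly zero. Water, protein and
  a deliberately band-free, fat-independent tracer (`inert`) complete
  the matrix.
* **Spectra** (`generate_spectra()`): clean spectrum = smooth baseline
  plus, per constituent, concentration × a sum of Gaussian bands
  (fat at 1205/1727/1797 nm, water and protein at 1454/1930 nm — the
  features visible in living-larva spectra); observed spectrum =
  $a + b\,\mathrm{clean} + \varepsilon$ with per-sample uniform scatter
  ($a \sim U(-0.05, 0.05)$ AU, $b \sim U(0.8, 1.2)$) and iid noise
  (default SD 0.002 AU). Band shapes are Gaussian with 30–60 nm widths
  because only peak positions are published; the scatter ranges are
  chosen so that scatter correction matters.
* **Group fat means** are not published per group (only the pooled range
  7.4–16.2 g/100 g, SD ≈ 2.3, and a few narrative values), so the
  generator fixes one set of means consistent with the narrative
  ordering — coconut/flaxseed-enriched groups highest (CF15 at 16.1,
  CF20 at 15.9), high-protein groups lowest (PPF6 at 7.6) — with a
  within-group SD of 0.4.
* **The canonical case study** (`make_case_study()`): 15 groups × 8
  samples, split 80/40 with every group in both sets, on a 1100–2100 nm
  grid at 2 nm (501 points). A single master seed expands to per-stage
  child seeds by fixed offsets, so each stage is independently
  reproducible and the same seed yields byte-identical CSVs.

What the generator does **not** emulate: instrument line shape,
wavelength-dependent (non-affine) scattering, water-band saturation,
temperature shifts of the O–H bands, and between-larva packing effects.
Consequently, passing the parameter-recovery tests shows the pipeline is
correct and well-posed on data satisfying its own assumptions; it does not
certify the accuracy levels reachable on real larvae. Conversely, the
band-free `inert` analyte shows the pipeline honestly failing where there
is no signal — the same qualitative regime as the published
palmitoleic/stearic failures.

## Numerical choices

* Wavelength grids must be strictly increasing and uniform (tolerance
  1e-9 nm); spectra with non-finite entries are rejected, not imputed.
* MSC refuses spectra whose regression slope against the reference falls
  below 1e-12 (flat spectrum), naming the sample.
* NIPALS needs no inner iteration for a univariate response; the
  deflation-exhaustion threshold is 1e-12 relative to the centered
  problem scale.
* SG derivative weights come from explicit least-squares solves per
  window geometry; interior points use a single precomputed convolution
  stencil.
* Ties in latent-variable selection and in best-model selection resolve
  toward fewer components / lower RMSEP, in that order.
* Reports store full-precision values; rounding (3 decimals for
  R²/RMSE, 2 for RPD) is display-only.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline on the
canonical 120-sample, 501-wavelength case study (seconds on one core),
property tests on dozens of small seeded instances, and Monte-Carlo
checks of the generator at 10,000 draws. These sizes were chosen as the
smallest that exercise every code path with comfortable statistical
margins.

## A worked run

```{r example}
cs <- make_case_study(seed = 114)
run <- run_calibration(cs$calibration$spectra, cs$calibration$reference,
                       cs$validation$spectra, cs$validation$reference,
                       analytes = c("fat", "inert"))
run$fat$report
run$inert$report
```

```{r verify}
v <- verify_reference_tables()
table(v$family, v$pass)
```

## Limitations

* PLS1 only: one response per model (no PLS2, SIMPLS or kernel PLS), no
  outlier ellipses (Hotelling T², Q residuals), no jackknife coefficient
  tests.
* No wavelength selection or resampling between instrument grids; a model
  refuses spectra from a different grid rather than interpolating.
* The generator's scatter is affine by construction, which is exactly the
  model MSC inverts; real scatter is kinder to no method in particular.
* Published R²/RMSE values for real larvae are not reproducible from
  synthetic data; the package verifies the printed tables' internal
  arithmetic instead.
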