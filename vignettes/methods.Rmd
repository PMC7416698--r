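---
title: "Predicting foveal visual potential from photoreceptor structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting foveal visual potential from photoreceptor structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Blue cone monochromacy (BCM) is an X-linked congenital loss of L/M-cone
function with structurally retained — but non-functional — foveal cones.
Gene therapy delivered intravitreally would plausibly transduce only the
fovea, so the clinically decisive question is *per patient*: if therapy
restored function to the level the surviving photoreceptor structure can
support, how much foveal sensitivity (FS, in dB) and visual acuity (VA,
decimal) would be gained?

`fovecast` implements a structure-to-function prediction pipeline for this
question. Foveal photoreceptor structure is quantified from OCT B-scans;
two regression approaches predict function from structure; and *treatment
potential* is the difference between the prediction and the measured
(often non-detectable) function.

## The quantum-catch curve

The anchor model assumes surviving cones function in proportion to their
remaining quantum catch, which scales with outer nuclear layer (ONL)
thickness. Both functional targets are fit with

$$y = y_0 + a\,\log_{10}(\mathrm{ONL}),$$

with frozen clinical coefficients $(y_0, a) = (-12.01, 17.38)$ for FS (dB)
and $(-1.07, 0.91)$ for VA (decimal). The base of the logarithm is 10: that
choice is forced by arithmetic, since $-1.07 + 0.91\log_{10}(90) = 0.708$,
which reproduces the clinical worked example (decimal 0.71, Snellen 20/25)
while natural log does not. "Non-linear regression" for this model class is
implemented as ordinary least squares after the log transform — the model
is linear in $\log_{10}(x)$, so the optimum is identical, the fit is
deterministic, and coefficient standard errors follow the usual
$t_{n-2}$ theory. The RMSE stored with a fit uses divisor $n$ (differences
squared, averaged, rooted), matching how prediction ranges
($\pm 1.96\,\mathrm{RMSE}$) are defined throughout. Predictions are not
clipped: a negative predicted FS or VA is reported as-is with a warning and
read as "below measurable range".

## The two forest model families

Because the curve uses ONL alone, it cannot see outer-segment shortening.
Two random-forest regression families complement it:

* **Model I** uses segmentation features per sample: ONL, inner segment
  (IS), cone outer segment (COS) and RPE thicknesses, the count of
  gradient extrema between ELM and BrM (a proxy for how many distinct
  bands survive), the folded eccentricity $|e|$, and the interactions
  ONL·COS, ONL·$|e|$, COS·$|e|$. Eccentricity is folded because the
  7-point grid is symmetric and no nasal/temporal convention is stated;
  this is logged as an assumption. A flagged (undetectable) thickness is
  imputed as 0 with an indicator column — a missing band (e.g. an IS/OS
  defect) is *signal*, not missingness at random.
* **Model II** uses only the raw longitudinal reflectivity profile,
  resampled at fixed depths above BrM, plus $|e|$ as a position tag
  (included by default and toggleable; without it rows would be
  position-ambiguous).

The forest is a standard regression CART ensemble (bootstrap resamples,
variance-reduction splits, `floor(p/3)` candidate features per split,
minimum leaf size 2, 500 trees by default), implemented in C++ inside the
package because no forest package is available in the target environment;
all hyperparameters are config-exposed and fixed seeds make every fit
reproducible. Subject-level predictions average the subject's 21 row-level
predictions (3 scans × 7 eccentricities). Evaluation is leave-one-subject-out:
folds are defined by subject identity, so no held-out row can enter its own
training set, and the cross-validated RMSE supplies the
$\pm 1.96\,\mathrm{RMSE}$ prediction range.

A deliberate sizing choice: the reflectivity vector spans **0–240 µm**
above BrM (61 values at 4 µm) rather than a narrower 0–160 µm window. With
training ONL up to 150 µm the OPL band sits up to ~240 µm above BrM; a
160 µm window would truncate the main ONL signal for thick retinas and
leave Model II keying almost entirely on EZ/COST band positions (i.e. on
COS), which inverts the intended contrast between the model families. The
window is a config parameter.

## The synthetic world

No patient data are distributable, so the package states a synthetic world
with the statistical structure the analysis assumes and tests everything
against it. The generator's defaults are the stated conditions, chosen
once:

* **Training cohort**: 26 IRD subjects with foveal ONL log-uniform on
  24–150 µm plus 3 normals near the upper end (110–150 µm), ages 18–72 and
  22–32 years respectively.
* **COS coupling**: COS = 5 + 0.22·ONL plus Gaussian scatter whose SD is
  derived analytically from the log-uniform ONL mixture variance so that
  the population ONL–COS correlation equals 0.814. A 6 µm physical floor
  reflects that IRD patients with measurable cone function retain some
  outer segment (it also keeps rendered EZ and COST bands separable); the
  floor inflates the realized pooled correlation slightly, to ≈0.83,
  within the ±0.05 acceptance band.
* **Functional targets**: FS and VA follow the frozen curves plus noise
  (SD 1.5 dB for FS; 0.08 logMAR for VA, applied on the logMAR scale
  because acuity noise is multiplicative in MAR). The residual is
  decomposed as $\sqrt{\rho}\,z + \sqrt{1-\rho}\,\varepsilon$ where $z$ is
  the standardized COS deviation from the coupling line and $\rho = 0.5$:
  marginally the residual is still exactly $N(0, \mathrm{SD}^2)$ and
  independent of ONL (so zero-noise cohorts lie exactly on the reference
  curves and coefficient recovery is unbiased), but it is correlated with
  COS. This encodes the model's own physiology — quantum catch tracks
  outer-segment length as well as cell count — and it is what makes a
  COS-aware model (Model I) predict less recovery than ONL-anchored
  methods for thick-ONL/short-COS foveae.
* **BCM cohorts**: two cohorts of 8 (deletion, C203R); FS non-detectable;
  VA uniform on 0.08–0.25 decimal; COS uniform on 4.5–10.5 µm and
  independent of ONL; ONL uniform on 35–75 µm (deletion) versus
  65–115 µm (C203R) — the reported genotype difference in foveal
  persistence. No distributional detail exists for BCM VA or age, so these
  ranges are config-exposed stand-ins, not claims.
* **B-scan rendering**: each A-scan is a 0.05 baseline plus Gaussian bands
  (SD 2.5 µm ≈ 6 µm FWHM, typical SD-OCT axial resolution) at the depths
  of ILM, OPL, ELM, EZ, COST, RPE1 and RPE2/BrM implied by the thickness
  profiles, with RPE2/BrM globally strongest (relative amplitudes 0.25,
  0.45, 0.35, 0.8, 0.6, 0.7, 1.0 in that order) and additive Gaussian
  speckle
  (SD 0.02). Thickness profiles decline quadratically to −12 % (ONL) /
  −8 % (IS, COS) at ±0.75° and saturate beyond, so wide scans remain
  physically valid. The foveal pit leaves a 30 µm residual inner retina at
  the foveola and recovers ~150 µm at the rim with a Gaussian shoulder of
  half-width 0.4°; the depth window extends 40 µm below BrM so the
  alignment band is an interior peak, as in real scans with choroid
  beneath. Lateral calibration 1° = 288 µm is used only for rendering,
  never analysis. Two boundaries closer than 2 axial steps are a
  degenerate-geometry error, not a renderable scene.

What the generator does **not** emulate: eye-motion artifact, vessel
shadows, cystoid edema, foveal atrophy, age progression, or realistic
multiplicative speckle statistics. A green test therefore establishes that
the pipeline's logic is correct under the stated world, not that the
segmentation is robust to every clinical artifact.

## Segmentation choices

Clinical OCT segmentation of this kind is "computer-assisted", with no
single canonical algorithm; this package fixes one so it can be tested against the renderer's
stored ground truth:

1. Align every LRP so its strongest smoothed band (RPE2/BrM) sits at depth
   0; A-scans whose maximum lies at the matrix border are flagged as
   truncated and excluded.
2. Detect candidate bands as prominence-filtered local maxima (Gaussian
   smoothing SD 1 sample; prominence ≥ 15 % of the scan maximum) with
   quadratic sub-sample peak refinement.
3. Assign candidates to RPE1, COST, EZ, ELM, OPL with an order-preserving
   dynamic program scored by expected relative amplitude (tolerance 0.15)
   inside admissible depth windows, with penalties for skipping a role
   (1.5) or leaving a band unassigned (0.5). This lets a genuinely missing
   band (IS/OS defect) be *flagged* instead of forcing the next band into
   the wrong role.
4. A lateral pass flags depths jumping > 8 µm from the running median and
   interpolates flagged runs up to 5 A-scans; longer gaps stay flagged.
   Per-A-scan manual overrides mirror the "assisted" part of such a
   workflow.

An A-scan with fewer than 2 or more than 12 candidate bands is
unsegmentable (the latter catches speckle-only input); a scan with more
than half its A-scans unsegmentable is rejected. Foveola localisation is
automated (minimum of the smoothed inner-surface height, ties toward scan
centre) with a manual override, because a manual procedure
does not scale to simulation; thicknesses at the 7 eccentricities are
averaged over ±0.05° so the 0.25° grid is denoised without blurring.

Numerical edge cases: negative computed thicknesses are flagged rather
than clipped to zero; thickness flags propagate into features as
0-plus-indicator; an LRP window shorter than 3 samples is an error for
extrema counting.

## Treatment potential and chart arithmetic

Non-detectable FS is floored at 0 dB (once, before differencing; the
floor is configurable because a perimeter's true floor is
device-dependent), so FS potential equals the predicted sensitivity, also
reported in log units (10 dB = 1 log unit). VA potential is computed on
the logMAR scale. ETDRS lines gained round both acuities to the 0.1-logMAR
chart-line grid and difference them ×10, with half-grid ties rounded
toward better acuity — the only convention that reproduces both reference
examples (six lines to 20/25 and four lines to 20/40 from a 20/100
baseline). Snellen labels snap to the standard denominator set
10–200; acuities beyond the chart are flagged, not extrapolated. The
quoted-range convention for line endpoints (e.g. "four to seven lines")
does not reduce to one
obvious convention, so the package reports the delta range in decimal and
logMAR and does not claim to reproduce those endpoints.

Across-method comparisons use a Kruskal–Wallis rank test implemented from
the rank-sum formula with tie correction (it is part of the tested
surface, checked against an exhaustive permutation oracle and against the
base-R implementation), plus an optional Monte Carlo permutation p-value;
pairwise follow-ups are descriptive only.

## What the pipeline run produces

`run_pipeline(run_config())` simulates the cohorts, renders and
re-segments every B-scan (`mode = "fast"` skips imaging and samples the
ground truth directly — used for replicate studies), evaluates I-FS, I-VA,
II-FS, II-VA and both curve fits by leave-one-subject-out validation,
trains final models, predicts all 16 BCM subjects with all three methods,
and emits per-subject potential tables plus genotype-group summaries and
tests. On the default synthetic world the C203R across-method comparison
is the statistically significant one while the deletion comparison is not,
and COS-aware Model I predicts the least improvement for
thick-ONL/short-COS foveae — the qualitative pattern the method was built
to expose. On the rendered-image path, very short BCM outer segments
partially merge the EZ and COST bands; Model I then sees a flagged COS
(an IS/OS defect indicator) and Model II sees the merged-band reflectivity
itself, so the *fast* path is the one that isolates the model-family
contrast cleanly.

## Known limitations

* The forest implementation is deliberately minimal (no missing-value
  handling beyond the indicator convention, no variable importance).
* Segmentation amplitude priors assume the rendered band ordering; scans
  from devices with different band contrast would need re-tuning.
* The synthetic BCM world fixes plausible but unverifiable distributions
  for VA and age; conclusions about those quantities are conditional on
  the stated ranges.
* Leave-one-subject-out RMSE at n = 29 carries real sampling noise; the
  prediction ranges inherit it.
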