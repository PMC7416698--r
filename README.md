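# fovecast

Predicting foveal visual potential from photoreceptor structure on OCT,
with per-patient treatment-potential estimates for blue cone monochromacy
(BCM).

## The problem

BCM is an X-linked congenital loss of L/M-cone function. The foveal cones
are structurally present but silent, which makes the fovea a candidate for
intravitreal gene therapy — and raises the clinically decisive question:
**if therapy restored function to the level the surviving structure can
support, how much vision would each patient gain?**

`fovecast` answers it the way it is answered in structure–function
research on inherited retinal degenerations (IRDs):

1. Quantify foveal photoreceptor structure on OCT: outer nuclear layer
   (ONL), inner segment (IS), cone outer segment (COS) and RPE
   thicknesses, segmented from each longitudinal reflectivity profile
   (LRP) at seven eccentricities (0.25° grid) in three B-scans per
   subject.
2. Learn structure → function on an IRD training cohort (26 IRD + 3
   normal subjects) in which cones function in proportion to their
   remaining **quantum catch**. Three predictors are fit for each target
   (foveal sensitivity FS in dB; decimal visual acuity VA):
   - **Model I** — random-forest regression on segmentation features with
     ONL·COS and thickness·eccentricity interactions;
   - **Model II** — random-forest regression on the raw reflectivity
     vector;
   - **CF** — the quantum-catch log curve `y = y0 + a·log10(ONL)`, with
     clinical coefficients `FS = −12.01 + 17.38·log10(ONL)` and
     `VA = −1.07 + 0.91·log10(ONL)`.
   Models are validated by leave-one-subject-out cross-validation;
   prediction ranges are ±1.96·RMSE.
3. **Treatment potential** = prediction − measured function (with
   non-detectable FS floored at 0 dB), converted for VA into ETDRS chart
   lines gained and a predicted Snellen line.

Because no patient data are distributable, the package includes a
first-class synthetic-data module: cohort generators with the training
cohort's statistical structure (ONL 24–150 µm, ONL–COS correlation
r ≈ 0.814, functional targets on the log curves plus noise) and an OCT
B-scan renderer with ground-truth sidecars, so the entire pipeline —
alignment, foveola localisation, six-boundary segmentation, feature
extraction, modelling, potential reports — is testable end to end.

## Worked example

The clinical shortcut (two reference worked examples):

```r
library(fovecast)

va_from_onl(90)                       # 0.7083607  (decimal; rounds to 0.71)
nearest_chart_line(va_from_onl(90))   # "20/25"
etdrs_lines_gained(0.2, va_from_onl(90))  # 6  (from a 20/100 baseline)

va_from_onl(59)                       # 0.5414748  (rounds to 0.54)
nearest_chart_line(va_from_onl(59))   # "20/40"
etdrs_lines_gained(0.2, va_from_onl(59))  # 4

fs_from_onl(c(90, 59)) / 10           # 2.195474 1.876741  (log units of FS
                                      #  gain over a non-detectable floor)
```

A patient with 20/100 acuity but 90 µm of surviving foveal ONL is
predicted to reach ~20/25 — a six-line gain — while the same acuity with
59 µm of ONL supports ~20/40 (four lines). Both FS gains exceed 1.5 log
units.

The full pipeline on the synthetic world:

```r
res <- run_pipeline(run_config(seed = 11, outdir = "fovecast_out"))
res$evaluations[["I-FS"]]
#> LOSO evaluation of Model I-FS: 29 folds, RMSE 1.666
res$cf_fits$FS
#> Quantum-catch log fit (FS): y = -12.83 + 17.73 * log10(ONL)
#>   n = 29, rmse = 1.78, p(a) = 3.13e-13
subset(res$group_comparison$tests, target == "FS")
#>          group target      H df      p_chisq       p_perm
#> 1 BCM_deletion     FS  2.555  2 2.787333e-01 0.2738630685
#> 3    BCM_C203R     FS 20.480  2 3.571285e-05 0.0004997501
```

The synthetic training cohort recovers the clinical curve coefficients,
and the across-method comparison is strongly significant for the C203R
genotype but not the deletion genotype at this seed (group-level
significance for the 8-subject deletion cohort fluctuates across seeds;
the C203R effect is stable): C203R foveae keep thick ONL but short COS,
so the COS-aware Model I predicts less improvement than the ONL-anchored
curve fit.

Command line:

```sh
Rscript -e 'fovecast::fovecast_cli()' simulate cohort --group training --seed 1 --out cohort.csv
Rscript -e 'fovecast::fovecast_cli()' run-all --seed 1 --outdir out/
```

## Package layout

- `R/synthetic_data.R` — cohort generators, ground-truth retina geometry,
  B-scan renderer
- `R/oct_processing.R` — downsampling, BrM alignment, foveola detection,
  six-boundary segmentation, thicknesses, extrema counts, feature
  extraction
- `R/models.R` + `src/forest.cpp` — design matrices, regression forest,
  LOSO evaluation
- `R/curvefit.R` — quantum-catch log fits and the frozen clinical
  formulas
- `R/potential.R` — treatment potential, ETDRS arithmetic,
  Kruskal–Wallis comparison
- `R/pipeline.R`, `R/io.R`, `R/cli.R` — end-to-end runs, TSV/CSV formats,
  CLI
- `vignettes/methods.Rmd` — the model, the synthetic world and every
  numerical choice, with rationale
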