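# lvcine

Contour-based quantification of mouse left-ventricular (LV) cine MRI, and
prediction of post-infarction adverse remodelling from early measurements.

After experimental myocardial infarction (ligation of the left anterior
descending coronary artery), the mouse LV dilates, hypertrophies and loses
contractile function over the following weeks. Cine MRI — an ECG-gated movie
of the cardiac cycle in contiguous 1 mm short-axis slices, typically ≥ 20
phases per cycle — is the reference technique for tracking this
longitudinally in individual animals. `lvcine` is aimed at labs running such
studies: it takes manually traced epicardial and endocardial borders (the
ImageJ-style workflow, exported to a simple CSV dialect) and computes the
standard global measurements, the infarct size, the quality-control checks,
and the early-to-late prediction statistics, with a synthetic phantom and
cohort generator for validating the whole chain against known ground truth.

## What it computes

**Volumetry (slice summation / Simpson's rule).** Per slice and phase, the
endocardial area gives the cavity volume and the epi−endo area difference
the myocardial volume, each multiplied by the slice thickness and summed
over slices. End-diastole (ED) and end-systole (ES) are the phases of
maximal and minimal total cavity volume. From the cavity volumes EDV and
ESV:

    SV = EDV − ESV          EF% = SV / EDV × 100

LV mass is the myocardial volume times the myocardial specific gravity,
1.05 mg/mm³, computed independently at ED and ES and reported as their
average.

**Infarct size.** A mature infarct appears as thinned, akinetic wall.
With marked akinetic arcs of length I_ep, I_en on the epicardial and
endocardial borders and circumferences T_ep, T_en, at ED:

    Infarct size (%) = 1/NSLICES · Σ_slices ½(I_ep/T_ep + I_en/T_en) × 100

where NSLICES counts every traced LV slice (non-infarcted slices contribute
zero).

**Quality control.** (i) the ED- and ES-derived masses must agree within 5%
(symmetric percentage difference); (ii) inter-observer agreement (Pearson r,
mean difference, 95% Bland–Altman limits of agreement); (iii) correlation of
calculated mass against autopsy mass.

**Remodelling prediction.** Over the MI animals: the univariate correlation
table of the five week-1 variables (LV mass, EDV, ESV, EF, infarct size)
against the four week-4 outcomes, with two-sided p-values from
t = r√(n−2)/√(1−r²); simple OLS regression (e.g. week-4 EDV on week-1 ESV);
and stepwise forward selection by partial-F test with entry p < 0.05.

**Synthetic data.** `generate_phantom()` builds a truncated half-ellipsoid
LV with a volume-conserving contracting wall and an optional thinned,
akinetic infarct wedge, with analytic ground truth; `generate_cohort()`
simulates a 25 MI + 11 sham cohort whose week-4 outcomes are linear in
week-1 ESV (default link: `lv_edv_wk4 = 1.33 · lv_esv_wk1 + 26 + ε`).

## Worked example

```r
library(lvcine)

## a phantom with a 90-degree thinned akinetic wedge
ph  <- generate_phantom(phantom_spec(infarct = list(theta_start = 20,
                                                    theta_extent = 90)))
summary(quantify(ph$study))
#> LV volumetry: phantom01 @ week1
#>   EDV 58.75 ul (phase 0)   ESV 32.08 ul (phase 10)
#>   SV  26.67 ul   EF 45.39 %
#>   LV mass 85.03 mg (ED 84.96, ES 85.1)
#>   ED/ES mass discrepancy 0.156 % (QC pass)

infarct_size(ph$study)
#> Infarct size: phantom01 @ week1
#>   22.44 % of LV myocardium at end-diastole (phase 0), over 7 slice(s) [all]
```

The infarcted phantom ejects less (EF 45% vs ~60% for the healthy default)
because the wedge neither contracts nor thickens; the infarct percentage
sits below the 25% angular fraction because the thinned wall shortens the
epicardial arc relative to the healthy sector. The ED/ES mass discrepancy
stays far inside the 5% QC bound.

```r
## a simulated cohort and the week-1 -> week-4 prediction analysis
sim <- generate_cohort(cohort_spec(seed = 42))
ols_fit(sim$cohort, "lv_edv_wk4", "lv_esv_wk1")
#> OLS fit (MI animals, n = 25):
#>   lv_edv_wk4 = 1.327 * lv_esv_wk1 + 25.85
#>   r^2 = 0.9744, residual SD = 2.33
#>   SE(slope) = 0.0449, SE(intercept) = 2.43

stepwise_forward(sim$cohort, "lv_edv_wk4", WK1_PREDICTORS)
#> Stepwise forward selection for lv_edv_wk4 (entry p < 0.05, n = 25)
#>  step   variable partial_f           p r_squared_after
#>     1 lv_esv_wk1  875.4005 8.25085e-20       0.9743989
```

The fitted line recovers the generating relationship (slope 1.33,
intercept 26) within sampling error, and forward selection enters week-1
ESV alone — no other week-1 variable adds a significant partial
contribution — mirroring how such a cohort is screened for the best early
predictor of late dilatation.

A command-line wrapper over the same pipeline
(`quantify` / `predict` / `simulate` subcommands) is installed at
`system.file("scripts", "lvcine.R", package = "lvcine")`.

## Package layout

- `R/contours.R` — contour/study types, polygon geometry, CSV dialect I/O
- `R/volumetry.R` — volumes, mass, ED/ES detection, `quantify()`
- `R/infarct.R` — arc-fraction infarct sizing
- `R/qc.R` — the three accuracy checks
- `R/remodelling.R` — correlation table, OLS, stepwise forward selection
- `R/phantom.R`, `R/cohort.R` — synthetic generators with ground truth
- `R/cli.R` — batch orchestration (`run_quantify`, `run_predict`,
  `run_simulate`)
- `vignettes/lv-quantification-methods.Rmd` — models, assumptions and
  design choices
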