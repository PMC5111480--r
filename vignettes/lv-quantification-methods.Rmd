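---
title: "Methods: LV cine-MRI quantification and remodelling prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LV cine-MRI quantification and remodelling prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcine)
```

`lvcine` quantifies mouse left-ventricular structure and function from
manually traced short-axis cine-MRI contours and runs the early-to-late
remodelling prediction analysis used in longitudinal infarction studies.
This vignette records the models, the numerical conventions and the design
choices that were genuinely open, so that a user knows exactly what every
number means.

## The measurement model

### Slice-summation volumetry

All geometry lives in physical units (mm) in the short-axis imaging plane;
pixel-to-mm conversion is an ingest concern, outside the package. Each
traced border is an ordered polygon, implicitly closed (the file never
repeats the first vertex). Polygon area uses the shoelace formula, with
validation rejecting degenerate (< 3 vertices), duplicated-vertex, and
self-intersecting tracings; arc and circumference lengths are Euclidean
polyline sums along the same polygon.

Per slice and phase the cavity area is the endocardial polygon area and the
myocardial area the epi−endo difference; totals are area × slice thickness
summed over slices (Simpson slice summation; mm³ and µl are treated as the
same unit). The package requires contiguous slice coverage and a complete
epi/endo pair on every traced slice and phase: a silently missing interior
slice would corrupt the sum, so it is an error rather than a skip. Whether
basal outflow-tract slices belong in the stack is a tracing decision; the
package quantifies exactly what is traced.

End-diastole and end-systole are defined **globally** as the phases of
maximal and minimal total cavity volume, not per-slice extrema — the
standard cine convention, which guarantees SV ≥ 0 — with ties broken to
the lowest phase index (a flat cycle yields ED = ES and EF = 0). LV mass is
myocardial volume × 1.05 mg/mm³ (myocardial specific gravity), computed
independently at ED and ES; the reported mass is their mean, and their
symmetric percentage difference 100·|m_ED − m_ES| / mean(m_ED, m_ES) feeds
the quality-control rule (bound 5% by default). The symmetric denominator
makes pass/fail independent of argument order; with an asymmetric
denominator the same pair of masses could pass in one order and fail in the
other.

### Infarct size

Infarct size is the slice-averaged mean of the epicardial and endocardial
akinetic-arc fractions at end-diastole:

$$\mathrm{IS}(\%) = \frac{1}{N_{slices}}\sum_{s}
  \tfrac12\!\left(\frac{I_{ep}}{T_{ep}} + \frac{I_{en}}{T_{en}}\right)
  \times 100.$$

Arcs are stored as vertex-index ranges on the border polygon itself, so an
arc length can never exceed the circumference it is divided by. Two
conventions needed fixing:

* **N_slices counts every traced LV slice** (slices without arcs contribute
  zero). The alternative — averaging only over infarct-bearing slices —
  would report a small apical infarct as a large percentage of the whole
  ventricle; it is available as `nslices = "infarcted"` but is not the
  default.
* **Disjoint arcs on one border are summed** before dividing by the
  circumference; an arc covering every vertex is measured as the full
  closed perimeter.

Arcs are required on the end-diastolic tracings; arcs found only on other
phases raise an error pointing the user at the ED phase, rather than
silently measuring a phase the statistic is not defined on.

### Quality control

Three accuracy checks are bundled: the ED/ES mass rule above (the only
gating check), inter-observer agreement, and calculated-vs-autopsy mass
correlation. For observers the package reports, per variable, the Pearson
r, the mean difference and the 95% Bland–Altman limits of agreement
(mean ± 1.96·SD of the paired differences). The limits go beyond a bare
correlation deliberately: r is blind to a constant bias between observers,
which the limits expose. They are reported but never gate.

## The prediction analysis

Five week-1 predictors (LV mass, EDV, ESV, EF, infarct size) are screened
against four week-4 outcomes (mass, ESV, EDV, EF) over the MI animals
only; sham animals are carried in the table as a reference mean (they
appear as the open-square reference point in the regression plot) but are
never fitted, since they share no remodelling process with the infarcted
group. Pearson correlations get two-sided p-values from the t transform
t = r√(n−2)/√(1−r²) with per-pair complete-case n. No multiple-testing
correction is applied across the 20 cells — the table is a screening
instrument, and each cell is read as a univariate result; a Bonferroni
column is available behind a flag.

Simple regression is ordinary least squares via `stats::lm()`, reported as
slope, intercept, their standard errors, r², residual SD and n.

Stepwise forward selection enters, at each step, the candidate with the
smallest partial-F p-value as long as that p-value is below `entry_alpha`
(default 0.05), with no removal step — the conventional pure-forward
default of mainstream statistics packages; the exact criterion is a
configuration knob because reported analyses rarely state it. Ties break
by declared candidate order, making the procedure deterministic;
rank-deficient additions (e.g. a duplicated column) are skipped with a
warning. All steps are fitted on the same complete-case rows so partial-F
tests are nested properly.

## The synthetic generators

The study's raw tracings and cohort are not distributable, so validation
rests on two generators with known ground truth.

### Cine phantom

The LV is a truncated half-ellipsoid cavity (equatorial semi-axis 2 mm,
long axis 7 mm — a typical mouse LV) with a 1 mm wall, cut into 7
contiguous 1 mm short-axis slices and sampled over 20 cardiac phases,
matching standard murine acquisition geometry. Contraction is radial:
the endocardial radius scales by 1 − c(t) with a smooth cosine profile
peaking mid-cycle; the default peak contraction 0.37 yields EF ≈ 60%,
typical of a healthy mouse. Outside any infarct the epicardial radius is
set so each slice's shell ring area is conserved exactly
(r_ep = √(r_en² + Δ)), which makes ED and ES mass agree to rounding error —
this is what gives the 5% QC rule its margin, and it holds for the polygon
areas too because a regular n-gon's area is proportional to r².

An infarct is a wedge of configurable angular extent: the wall is thinned
by a factor κ (default 0.6) and, if akinetic (default), the endocardial
radius in the wedge is frozen at its ED value across all phases. The
infarct-to-healthy transition is smoothed over 10°, a numerical necessity
that keeps the polygons simple where the frozen and contracted radii meet.
Vertices inside the nominal wedge carry the infarct flag on both borders.
One consequence worth knowing: with κ < 1 the epicardial arc fraction is
genuinely below the wedge's angular fraction (the thinned wall shortens
the epicardial arc relative to the healthy sector), so a 90° wedge reads
slightly under 25%; the package's tests check the un-thinned wedge against
25% and the thinned one against a dense arc-length oracle.

The ground-truth record holds the analytic cavity volumes over the covered
extent (closed form without infarct, dense continuous-model integration
with), EF, shell volume and mass, true ED/ES phases, and the wedge's
angular fraction. Contours are emitted at 1e-6 mm precision — the file
dialect's precision — so a write/read round trip is the identity, and all
randomness (optional tracing noise, observer jitter) flows from explicit
seeds.

What the phantom does **not** emulate: papillary muscles, through-plane
motion, trabeculation, irregular infarct borders, and observer bias (the
noise model is zero-mean jitter). Passing phantom tests therefore
demonstrates that the measurement chain is correct on clean geometry, not
that manual tracing of real images is unbiased.

### Cohort simulator

Each of 25 MI animals draws a latent infarct-severity burden uniform on
10–45 percentage points; week-1 variables are linear in severity plus
Gaussian noise, and week-4 outcomes are linear in week-1 ESV plus noise.
The EDV link defaults to `lv_edv_wk4 = 1.33·lv_esv_wk1 + 26 + ε` with
ε-SD 2.5 µl — the remodelling relationship the prediction analysis
targets, at a noise level giving r² ≈ 0.97 — while the remaining links and
the severity-to-week-1 coefficients are illustrative choices of plausible
murine physiology (week-1 ESV ≈ 29–67 µl, mass ≈ 100–135 mg at week 4),
documented as such. Ejection fractions are computed from the simulated
volumes, so EF ∈ [0, 100] holds whenever the volumes are physiological.
Eleven sham animals scatter with 5% CV around healthy reference means
(EDV 56 µl, ESV 20 µl, mass 92 mg, infarct 0%).

Rows violating the physiological invariants are redrawn; a spec whose
per-row violation probability exceeds 1% (estimated on a 4 000-row
vectorised draw, stable to ≈ 0.15%) is rejected with advice to reduce the
noise, rather than silently censoring the distribution. The ground truth
records the generating coefficients, the severities, and the correlation
between week-1 ESV and week-4 EDV implied by the coefficients, so tests
can check convergence of the empirical correlation (within ±0.01 at
n = 10 000).

## Numerical choices and degenerate inputs

* Index conventions: slices 0-based base→apex, phases 0-based, all ranges
  half-open. An arc over k+1 vertices spans k polygon edges, so marked
  regions are measured to within one vertex spacing; at the default 96
  vertices per contour this is ≈ 1% of a 90° wedge.
* Polygon simplicity is checked by exact all-pairs segment intersection
  (vectorised, O(n²) per polygon); collinear touching counts as invalid.
* Self-consistency tolerances in the test suite: shoelace vs
  fan-triangulation 1e-9 relative; slice-summed phantom volumes within 3%
  of the continuous quadrature oracle at 1 mm slices, with the gap
  shrinking monotonically at 0.5 and 0.25 mm (checked at 512 vertices per
  contour so polygon-area deficit does not mask the slice-discretisation
  trend); infarct of an un-thinned 90° wedge within 2 percentage points of
  25%.
* Statistical suite sizes, chosen to keep the default test run around a
  minute while leaving ≥ 3σ margins on every asserted rate: 1 000 null
  cohorts (n = 25) for the 5% type-I check of the correlation test
  (asserted within 3–7%); 500 cohorts each for the forward-selection
  consistency and null runs; 1 000 replicates for OLS slope bias < 1%.
* The forward-selection consistency simulation ("the generating predictor,
  and only it, in ≥ 95% of cohorts") uses entry_alpha = 0.005 with four
  pure-noise candidates. This is a design necessity, not a tuning: with
  k − 1 noise candidates the family-wise false-entry chance at threshold α
  is ≈ 1 − (1−α)^(k−1), so at α = 0.05 no forward procedure can recover
  exactly the true predictor 95% of the time; α = 0.005 puts the expected
  exact-recovery rate near 98%. The null-rate simulation keeps the default
  α = 0.05 and checks the empty-model rate against (1−α)^k.
* Degenerate inputs fail loudly and specifically: constant columns name
  the offending pair; single-phase studies cannot define ED/ES; autopsy
  correlation refuses < 3 pairs; non-positive masses and volumes are
  errors, not NaNs.

## Known limitations

* Manual-tracing vertex counts, noise magnitude and observer bias in real
  murine data are unknown; the generator defaults are order-of-magnitude
  choices and every validation statement is conditional on the generator's
  model.
* No papillary-muscle convention, regional wall-motion scoring, diastolic
  indices, DICOM ingestion or automatic segmentation — the package starts
  from tracings.
* The infarct statistic is the arc-fraction measure only; histological and
  late-gadolinium-enhancement sizing are out of scope.
* The prediction module implements univariate screening, simple OLS and
  forward selection; longitudinal mixed-effects modelling is deliberately
  not included.
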