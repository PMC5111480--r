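Package: lvcine
Title: Left-Ventricular Cine-MRI Volumetry, Infarct Sizing and Remodelling
    Prediction for Mouse Models of Myocardial Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Contour-based quantification of mouse left-ventricular (LV)
    short-axis cine MRI: slice-summation (Simpson) cavity and myocardial
    volumes, LV mass via myocardial specific gravity, end-diastole and
    end-systole detection, stroke volume and ejection fraction, infarct
    size from marked akinetic arc fractions, and quality-control checks
    (end-diastolic vs end-systolic mass agreement, inter-observer
    agreement, calculated-vs-autopsy mass correlation). Includes the
    week-1 to week-4 adverse-remodelling prediction analysis (univariate
    correlation table, ordinary least-squares regression, stepwise
    forward selection) and two synthetic-data generators: a truncated
    half-ellipsoid cine LV phantom with analytic ground truth and a
    cohort simulator with known linear remodelling structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
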