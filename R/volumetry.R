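#' Myocardial specific gravity, mg/mm^3
#'
#' Density constant converting myocardial volume to mass.
#' @export
MYOCARDIAL_SPECIFIC_GRAVITY <- 1.05

#' Total myocardial (wall) volume at one cardiac phase
#'
#' Slice-summation volumetry: per slice, the myocardial area is the area
#' between the epicardial and endocardial borders; the total volume is the
#' sum of per-slice areas times the slice thickness.
#'
#' @param study A [cine_study()].
#' @param phase 0-based phase index present in the study.
#' @return Volume in mm^3.
#' @export
myocardial_volume <- function(study, phase) {
  sum(slice_areas(study, phase)$myocardial_area) * study$slice_thickness
}

#' LV cavity (blood-pool) volume at one cardiac phase
#'
#' Sum over slices of the endocardial area times slice thickness. mm^3 and
#' microlitres are the same physical unit; cavity volumes are reported in ul.
#'
#' @inheritParams myocardial_volume
#' @return Volume in ul.
#' @export
cavity_volume <- function(study, phase) {
  sum(slice_areas(study, phase)$endo_area) * study$slice_thickness
}

slice_areas <- function(study, phase) {
  stopifnot(inherits(study, "cine_study"))
  if (!phase %in% study$phases)
    stop(sprintf("phase %s not present in study (phases: %s)", phase,
                 paste(study$phases, collapse = ", ")))
  epi <- vapply(study$slices, function(s)
    polygon_area(get_tracing(study, s, phase, "epicardial")$vertices,
                 check = FALSE), numeric(1L))
  endo <- vapply(study$slices, function(s)
    polygon_area(get_tracing(study, s, phase, "endocardial")$vertices,
                 check = FALSE), numeric(1L))
  data.frame(slice = study$slices, epi_area = epi, endo_area = endo,
             myocardial_area = epi - endo)
}

#' Convert myocardial volume to LV mass
#'
#' Multiplies a myocardial volume by the myocardial specific gravity of
#' 1.05 mg/mm^3.
#'
#' @param volume_mm3 Myocardial volume in mm^3; must be positive.
#' @return Mass in mg.
#' @examples
#' lv_mass(100)  # 105 mg
#' @export
lv_mass <- function(volume_mm3) {
  if (!is.numeric(volume_mm3) || anyNA(volume_mm3) || any(volume_mm3 <= 0))
    stop("myocardial volume must be positive (mm^3)")
  volume_mm3 * MYOCARDIAL_SPECIFIC_GRAVITY
}

#' Detect end-diastolic and end-systolic phases
#'
#' End-diastole is the phase of maximal summed cavity volume and end-systole
#' the phase of minimal summed cavity volume, a global definition over the
#' whole stack rather than per-slice extrema; ties break to the lowest phase
#' index. A flat (non-contracting) cycle therefore yields `ed == es`.
#'
#' @param study A [cine_study()] with at least two phases.
#' @return Named integer vector `c(ed = ..., es = ...)` of 0-based phases.
#' @export
detect_ed_es <- function(study) {
  stopifnot(inherits(study, "cine_study"))
  if (length(study$phases) < 2L)
    stop("ED/ES detection needs at least 2 cardiac phases")
  vols <- vapply(study$phases, function(p) cavity_volume(study, p), numeric(1L))
  c(ed = study$phases[which.max(vols)], es = study$phases[which.min(vols)])
}

#' Quantify global LV function from a cine study
#'
#' Full contour-based volumetry of one study: detects end-diastole (ED) and
#' end-systole (ES), computes the cavity volumes EDV and ESV by slice
#' summation, stroke volume SV = EDV - ESV, ejection fraction
#' EF = SV/EDV x 100, and LV mass from the myocardial shell volume at ED and
#' ES separately (specific gravity 1.05 mg/mm^3). The reported mass is the
#' average of the two independent estimates; their discrepancy feeds the
#' quality-control check ([mass_agreement_check()]).
#'
#' @param study A [cine_study()].
#' @return An object of class `lv_volumetry` with fields `edv`, `esv`, `sv`
#'   (ul), `ef` (percent), `mass_ed`, `mass_es`, `mass_avg` (mg), `ed_phase`,
#'   `es_phase`, and a `per_slice` table of cavity volume (ul) and myocardial
#'   area (mm^2) for every slice and phase.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_phases = 6, vertices_per_contour = 48))
#' quantify(ph$study)
#' @export
quantify <- function(study) {
  stopifnot(inherits(study, "cine_study"))
  phases <- detect_ed_es(study)
  ed <- phases[["ed"]]; es <- phases[["es"]]
  per_slice <- do.call(rbind, lapply(study$phases, function(p) {
    a <- slice_areas(study, p)
    data.frame(slice = a$slice, phase = p,
               cavity_volume_ul = a$endo_area * study$slice_thickness,
               myocardial_area_mm2 = a$myocardial_area)
  }))
  edv <- cavity_volume(study, ed)
  esv <- cavity_volume(study, es)
  mass_ed <- lv_mass(myocardial_volume(study, ed))
  mass_es <- lv_mass(myocardial_volume(study, es))
  structure(
    list(subject_id = study$subject_id, timepoint = study$timepoint,
         edv = edv, esv = esv, sv = edv - esv,
         ef = if (edv > 0) (edv - esv) / edv * 100 else 0,
         mass_ed = mass_ed, mass_es = mass_es,
         mass_avg = (mass_ed + mass_es) / 2,
         ed_phase = ed, es_phase = es, per_slice = per_slice),
    class = "lv_volumetry")
}

#' @export
print.lv_volumetry <- function(x, digits = 4, ...) {
  cat(sprintf("LV volumetry: %s @ %s\n", x$subject_id, x$timepoint))
  cat(sprintf("  EDV %s ul (phase %d)   ESV %s ul (phase %d)\n",
              signif(x$edv, digits), x$ed_phase,
              signif(x$esv, digits), x$es_phase))
  cat(sprintf("  SV  %s ul   EF %s %%\n", signif(x$sv, digits),
              signif(x$ef, digits)))
  cat(sprintf("  LV mass %s mg (ED %s, ES %s)\n", signif(x$mass_avg, digits),
              signif(x$mass_ed, digits), signif(x$mass_es, digits)))
  invisible(x)
}

#' @export
summary.lv_volumetry <- function(object, ...) {
  print(object, ...)
  d <- mass_agreement_check(object)
  cat(sprintf("  ED/ES mass discrepancy %.3g %% (QC %s)\n",
              d$discrepancy_pct, if (d$pass) "pass" else "FAIL"))
  invisible(object)
}

#' One-row data frame of the global measurements
#'
#' @param x An `lv_volumetry` result.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return A one-row data frame with columns `subject_id`, `timepoint`,
#'   `edv_ul`, `esv_ul`, `sv_ul`, `ef_pct`, `mass_mg`, `ed_phase`, `es_phase`.
#' @export
as.data.frame.lv_volumetry <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(subject_id = x$subject_id, timepoint = x$timepoint,
             edv_ul = x$edv, esv_ul = x$esv, sv_ul = x$sv, ef_pct = x$ef,
             mass_mg = x$mass_avg, ed_phase = x$ed_phase, es_phase = x$es_phase)
}

#' Serialise a volumetry result to JSON
#'
#' @param x An `lv_volumetry` result.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
volumetry_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "lv_volumetry"))
  obj <- unclass(x)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
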