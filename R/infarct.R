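#' Infarct size from marked akinetic arcs
#'
#' Computes infarct size as a percentage of the LV myocardium at
#' end-diastole. Per slice, the marked akinetic arc lengths on the epicardial
#' and endocardial borders (I_ep, I_en) are each divided by the full border
#' circumference (T_ep, T_en) and the two fractions averaged; the infarct
#' size is the mean of this per-slice fraction over the slices, times 100:
#'
#'   Infarct size (%) = 1/NSLICES * sum( (I_ep/T_ep + I_en/T_en) / 2 ) * 100
#'
#' By default NSLICES counts every traced LV slice, so slices without marked
#' arcs contribute zero; `nslices = "infarcted"` restricts the average to
#' slices carrying at least one arc (an alternative reading that inflates
#' small apical infarcts and is not the default).
#'
#' Multiple disjoint arcs on one border are summed before dividing by the
#' circumference. Arcs are read from the tracings at the detected
#' end-diastolic phase; if arcs exist only on other phases this is an error
#' prompting the user to mark the end-diastolic tracings.
#'
#' @param study A [cine_study()] whose ED-phase tracings carry infarct arcs
#'   (possibly none anywhere, giving 0%).
#' @param nslices `"all"` (default) or `"infarcted"`; see Details.
#' @return An object of class `lv_infarct` with the per-slice table
#'   (`i_ep`, `t_ep`, `i_en`, `t_en` in mm and the unitless `slice_fraction`),
#'   `n_slices`, and the overall `infarct_pct`.
#' @export
infarct_size <- function(study, nslices = c("all", "infarcted")) {
  stopifnot(inherits(study, "cine_study"))
  nslices <- match.arg(nslices)
  ed <- detect_ed_es(study)[["ed"]]

  has_arcs <- function(tr) nrow(tr$infarct_arcs) > 0L
  any_ed <- any(vapply(study$tracings, function(tr)
    tr$phase_index == ed && has_arcs(tr), logical(1L)))
  any_other <- any(vapply(study$tracings, function(tr)
    tr$phase_index != ed && has_arcs(tr), logical(1L)))
  if (!any_ed && any_other)
    stop(sprintf(paste0(
      "infarct arcs are marked only on non-end-diastolic phases; ",
      "infarct size is defined at end-diastole (detected phase %d) - ",
      "please mark the arcs on the end-diastolic tracings"), ed))

  per <- do.call(rbind, lapply(study$slices, function(s) {
    epi <- get_tracing(study, s, ed, "epicardial")
    endo <- get_tracing(study, s, ed, "endocardial")
    data.frame(slice_index = s,
               i_ep = arc_total(epi), t_ep = perimeter(epi),
               i_en = arc_total(endo), t_en = perimeter(endo))
  }))
  per$slice_fraction <- (per$i_ep / per$t_ep + per$i_en / per$t_en) / 2
  keep <- if (nslices == "infarcted") per$slice_fraction > 0 else
    rep(TRUE, nrow(per))
  n <- sum(keep)
  pct <- if (n == 0L) 0 else 100 * mean(per$slice_fraction[keep])
  structure(
    list(subject_id = study$subject_id, timepoint = study$timepoint,
         per_slice = per, n_slices = n, infarct_pct = pct,
         ed_phase = ed, nslices_rule = nslices),
    class = "lv_infarct")
}

perimeter <- function(tr) polyline_length(tr$vertices, closed = TRUE)

arc_total <- function(tr) {
  if (!nrow(tr$infarct_arcs)) return(0)
  n <- nrow(tr$vertices)
  sum(apply(tr$infarct_arcs, 1L, function(a)
    # an arc spanning every vertex is the whole (closed) border
    polyline_length(tr$vertices, c(a[[1L]], a[[2L]]),
                    closed = a[[1L]] == 0L && a[[2L]] == n)))
}

#' @export
print.lv_infarct <- function(x, ...) {
  cat(sprintf("Infarct size: %s @ %s\n", x$subject_id, x$timepoint))
  cat(sprintf("  %.2f %% of LV myocardium at end-diastole (phase %d), over %d slice(s) [%s]\n",
              x$infarct_pct, x$ed_phase, x$n_slices, x$nslices_rule))
  invisible(x)
}

#' Tabular infarct report
#'
#' Per-slice arc lengths, circumferences and fractions plus the overall
#' infarct percentage, optionally written to CSV and/or JSON.
#'
#' @param result An `lv_infarct` object.
#' @param csv,json Optional output file paths.
#' @return The per-slice data frame with the overall percentage attached as
#'   attribute `infarct_pct`, invisibly when written to file.
#' @export
infarct_report <- function(result, csv = NULL, json = NULL) {
  stopifnot(inherits(result, "lv_infarct"))
  df <- result$per_slice
  attr(df, "infarct_pct") <- result$infarct_pct
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json))
    writeLines(jsonlite::toJSON(
      list(subject_id = result$subject_id, timepoint = result$timepoint,
           n_slices = result$n_slices, infarct_pct = result$infarct_pct,
           per_slice = df),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"), json)
  if (is.null(csv) && is.null(json)) df else invisible(df)
}
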