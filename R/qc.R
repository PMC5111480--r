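#' ED/ES mass agreement check
#'
#' Quality-control rule: the myocardial mass computed independently at
#' end-diastole and end-systole should differ by no more than a small
#' percentage (default bound 5%). The discrepancy is symmetric in the two
#' masses: `100 * |mass_ed - mass_es| / mean(mass_ed, mass_es)`.
#'
#' @param result An `lv_volumetry` object, or the ED mass in mg (with
#'   `mass_es` supplied).
#' @param mass_es ES mass in mg when `result` is a bare ED mass.
#' @param threshold_pct Acceptance bound in percent (default 5).
#' @return List with `discrepancy_pct` and logical `pass`.
#' @examples
#' mass_agreement_check(100, 104)  # 3.92%, pass
#' @export
mass_agreement_check <- function(result, mass_es = NULL, threshold_pct = 5) {
  if (inherits(result, "lv_volumetry")) {
    m1 <- result$mass_ed; m2 <- result$mass_es
  } else {
    m1 <- result; m2 <- mass_es
  }
  if (!is.numeric(m1) || !is.numeric(m2) || length(m1) != 1L ||
      length(m2) != 1L || anyNA(c(m1, m2)) || m1 <= 0 || m2 <= 0)
    stop("both masses must be single positive numbers (mg)")
  d <- 100 * abs(m1 - m2) / mean(c(m1, m2))
  list(discrepancy_pct = d, pass = d <= threshold_pct)
}

#' Inter-observer agreement statistics
#'
#' Compares per-subject measurement tables from two independent observers.
#' For every shared numeric variable it reports the Pearson correlation, the
#' mean difference (observer A minus observer B) and the 95% limits of
#' agreement, `mean(d) +/- 1.96 * sd(d)` over the paired differences
#' (Bland-Altman). The limits are reported alongside r because a correlation
#' alone cannot reveal a systematic bias between observers.
#'
#' @param measurements_a,measurements_b Data frames with an identifier column
#'   and the same numeric measurement columns, one row per subject.
#' @param id_col Name of the identifier column (default `"subject_id"`).
#' @return Data frame of class `observer_agreement` with one row per
#'   variable: `variable`, `n`, `pearson_r`, `mean_difference`, `loa_lower`,
#'   `loa_upper`.
#' @export
observer_agreement <- function(measurements_a, measurements_b,
                               id_col = "subject_id") {
  a <- as.data.frame(measurements_a)
  b <- as.data.frame(measurements_b)
  if (!id_col %in% names(a) || !id_col %in% names(b))
    stop("both tables need an identifier column '", id_col, "'")
  if (anyDuplicated(a[[id_col]]) || anyDuplicated(b[[id_col]]))
    stop("duplicated subject identifiers")
  if (!setequal(a[[id_col]], b[[id_col]]))
    stop("subject mismatch between observers: ",
         paste(union(setdiff(a[[id_col]], b[[id_col]]),
                     setdiff(b[[id_col]], a[[id_col]])), collapse = ", "))
  b <- b[match(a[[id_col]], b[[id_col]]), , drop = FALSE]
  vars <- intersect(names(a), names(b))
  vars <- vars[vars != id_col &
               vapply(a[vars], is.numeric, logical(1L)) &
               vapply(b[vars], is.numeric, logical(1L))]
  if (!length(vars)) stop("no shared numeric measurement columns")
  out <- do.call(rbind, lapply(vars, function(v) {
    d <- a[[v]] - b[[v]]
    r <- if (stats::sd(a[[v]]) == 0 || stats::sd(b[[v]]) == 0) NA_real_
         else stats::cor(a[[v]], b[[v]])
    m <- mean(d); s <- stats::sd(d)
    data.frame(variable = v, n = length(d), pearson_r = r,
               mean_difference = m,
               loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s)
  }))
  class(out) <- c("observer_agreement", class(out))
  out
}

#' Calculated-vs-autopsy mass correlation
#'
#' Pearson correlation between the image-derived LV mass and the mass
#' measured directly at autopsy, over paired subjects.
#'
#' @param calculated_mass,measured_mass Paired per-subject masses in mg,
#'   at least 3 pairs.
#' @return Pearson r.
#' @export
autopsy_correlation <- function(calculated_mass, measured_mass) {
  x <- as.numeric(calculated_mass); y <- as.numeric(measured_mass)
  if (length(x) != length(y)) stop("mass vectors must be paired (equal length)")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("autopsy correlation needs at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: one of the mass vectors is constant")
  stats::cor(x, y)
}

#' Assemble a per-study QC report
#'
#' Bundles the three accuracy checks: the ED/ES mass agreement rule (the
#' only gating check), optional inter-observer agreement statistics and an
#' optional calculated-vs-autopsy mass correlation.
#'
#' @param result An `lv_volumetry` object.
#' @param threshold_pct Mass-agreement bound in percent (default 5).
#' @param observer Optional [observer_agreement()] result.
#' @param autopsy_r Optional [autopsy_correlation()] result.
#' @return List of class `qc_report`.
#' @export
qc_report <- function(result, threshold_pct = 5, observer = NULL,
                      autopsy_r = NULL) {
  m <- mass_agreement_check(result, threshold_pct = threshold_pct)
  structure(
    list(subject_id = result$subject_id, timepoint = result$timepoint,
         mass_discrepancy_pct = m$discrepancy_pct, mass_check_pass = m$pass,
         mass_threshold_pct = threshold_pct,
         observer_agreement = observer, autopsy_correlation = autopsy_r),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %s @ %s\n", x$subject_id, x$timepoint))
  cat(sprintf("  ED/ES mass discrepancy %.3g %% (bound %g %%): %s\n",
              x$mass_discrepancy_pct, x$mass_threshold_pct,
              if (x$mass_check_pass) "pass" else "FAIL"))
  if (!is.null(x$observer_agreement)) {
    cat("  Inter-observer agreement:\n")
    print(as.data.frame(x$observer_agreement), row.names = FALSE)
  }
  if (!is.null(x$autopsy_correlation))
    cat(sprintf("  Calculated-vs-autopsy mass r = %.3f\n", x$autopsy_correlation))
  invisible(x)
}
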