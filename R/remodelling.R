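#' Week-1 predictor and week-4 outcome variable sets
#'
#' The canonical cohort-table variables: five early (week 1 post-MI)
#' predictors and four week-4 remodelling outcomes.
#' @export
WK1_PREDICTORS <- c("lv_mass_wk1", "lv_edv_wk1", "lv_esv_wk1", "lv_ef_wk1",
                    "is_wk1")

#' @rdname WK1_PREDICTORS
#' @export
WK4_OUTCOMES <- c("lv_mass_wk4", "lv_esv_wk4", "lv_edv_wk4", "lv_ef_wk4")

#' Validate a cohort table
#'
#' Checks the per-animal cohort schema: a unique `subject_id`, a `group`
#' column coded `MI`/`sham`, positive volumes and masses, ejection fractions
#' and infarct sizes within 0-100.
#'
#' @param cohort Data frame with the cohort schema columns.
#' @return The cohort, invisibly, with class `cohort_table` prepended.
#' @export
validate_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  need <- c("subject_id", "group", WK1_PREDICTORS, WK4_OUTCOMES)
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(cohort$subject_id))
    stop("duplicated subject_id in cohort table")
  if (!all(cohort$group %in% c("MI", "sham")))
    stop("group must be 'MI' or 'sham'")
  vol_mass <- c("lv_mass_wk1", "lv_edv_wk1", "lv_esv_wk1",
                "lv_mass_wk4", "lv_edv_wk4", "lv_esv_wk4")
  for (v in vol_mass)
    if (any(cohort[[v]] <= 0, na.rm = TRUE))
      stop("non-positive values in ", v)
  for (v in c("lv_ef_wk1", "lv_ef_wk4", "is_wk1"))
    if (any(cohort[[v]] < 0 | cohort[[v]] > 100, na.rm = TRUE))
      stop(v, " must lie in [0, 100]")
  if (!inherits(cohort, "cohort_table"))
    class(cohort) <- c("cohort_table", class(cohort))
  invisible(cohort)
}

mi_rows <- function(cohort) {
  cohort <- validate_cohort(cohort)
  out <- cohort[cohort$group == "MI", , drop = FALSE]
  if (!nrow(out)) stop("no MI rows in cohort (sham animals are not fitted)")
  out
}

# Pearson r and its two-sided p-value from the t transform
# t = r * sqrt(n - 2) / sqrt(1 - r^2), t ~ t_{n-2} under rho = 0.
pearson_rp <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant column")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Univariate correlation table of early predictors against late outcomes
#'
#' Pearson correlation of every (week-1 predictor, week-4 outcome) pair over
#' the MI animals, with two-sided p-values from the t transform
#' `t = r sqrt(n-2)/sqrt(1-r^2)` and per-pair complete-case n. Sham animals
#' are excluded from fitting by default. No multiple-testing correction is
#' applied across the cells, matching the univariate screening use; set
#' `bonferroni = TRUE` to add an adjusted-p column.
#'
#' @param cohort A cohort table (see [validate_cohort()]).
#' @param predictors,outcomes Column names; default the canonical sets.
#' @param bonferroni Add a `p_bonferroni` column (off by default).
#' @return Data frame of class `correlation_table` with columns `predictor`,
#'   `outcome`, `r`, `p`, `n`.
#' @export
correlation_table <- function(cohort, predictors = WK1_PREDICTORS,
                              outcomes = WK4_OUTCOMES, bonferroni = FALSE) {
  mi <- mi_rows(cohort)
  miss <- setdiff(c(predictors, outcomes), names(mi))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  grid <- expand.grid(predictor = predictors, outcome = outcomes,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    rp <- tryCatch(pearson_rp(mi[[grid$predictor[k]]], mi[[grid$outcome[k]]]),
                   error = function(e)
                     stop(sprintf("pair (%s, %s): %s", grid$predictor[k],
                                  grid$outcome[k], conditionMessage(e)),
                          call. = FALSE))
    data.frame(predictor = grid$predictor[k], outcome = grid$outcome[k],
               r = rp$r, p = rp$p, n = rp$n)
  })
  out <- do.call(rbind, res)
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p * nrow(out))
  class(out) <- c("correlation_table", class(out))
  out
}

#' Correlation table with per-outcome best-predictor flags
#'
#' The full predictor-by-outcome correlation table plus a `best` flag
#' marking, for each week-4 outcome, the week-1 predictor with the largest
#' absolute correlation.
#'
#' @inheritParams correlation_table
#' @return A `correlation_table` with an additional logical `best` column.
#' @export
table1_report <- function(cohort, bonferroni = FALSE) {
  tab <- correlation_table(cohort, bonferroni = bonferroni)
  tab$best <- FALSE
  for (o in unique(tab$outcome)) {
    idx <- which(tab$outcome == o)
    tab$best[idx[which.max(abs(tab$r[idx]))]] <- TRUE
  }
  tab
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  wide <- stats::reshape(
    transform(as.data.frame(x),
              cell = paste0(formatC(r, digits = digits, format = "fg"),
                            " (p=", formatC(p, digits = 2, format = "g"), ")",
                            if (!is.null(x$best)) ifelse(x$best, " *", "") else ""))[
                , c("predictor", "outcome", "cell")],
    idvar = "predictor", timevar = "outcome", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  if (!is.null(x$best)) cat("* highest |r| for that outcome\n")
  invisible(x)
}

#' Simple linear regression of a late outcome on an early predictor
#'
#' Ordinary least-squares fit of one week-4 outcome on one week-1 predictor
#' over the MI animals, e.g. the late end-diastolic volume on the early
#' end-systolic volume. Wraps [stats::lm()] and reports the slope, intercept,
#' their standard errors, r-squared, residual SD and n.
#'
#' @param cohort A cohort table.
#' @param outcome,predictor Column names.
#' @return Object of class `lv_ols` with `print`, `coef`, `predict`,
#'   `residuals` and `plot` methods; the underlying `lm` fit is in `$fit`.
#' @export
ols_fit <- function(cohort, outcome, predictor) {
  mi <- mi_rows(cohort)
  d <- mi[stats::complete.cases(mi[[outcome]], mi[[predictor]]),
          , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 complete rows")
  if (stats::sd(d[[predictor]]) == 0)
    stop("rank deficiency: predictor '", predictor, "' is constant")
  fit <- stats::lm(stats::reformulate(predictor, outcome), data = d)
  sm <- summary(fit)
  structure(
    list(outcome = outcome, predictor = predictor,
         slope = unname(stats::coef(fit)[predictor]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         se_slope = sm$coefficients[predictor, "Std. Error"],
         se_intercept = sm$coefficients["(Intercept)", "Std. Error"],
         r_squared = sm$r.squared, residual_sd = sm$sigma,
         n = nrow(d), fit = fit,
         sham_mean = sham_reference(cohort, c(predictor, outcome))),
    class = "lv_ols")
}

sham_reference <- function(cohort, vars) {
  sh <- cohort[cohort$group == "sham", vars, drop = FALSE]
  if (!nrow(sh)) return(NULL)
  colMeans(sh, na.rm = TRUE)
}

#' @export
print.lv_ols <- function(x, digits = 4, ...) {
  cat(sprintf("OLS fit (MI animals, n = %d):\n  %s = %s * %s + %s\n",
              x$n, x$outcome, signif(x$slope, digits), x$predictor,
              signif(x$intercept, digits)))
  cat(sprintf("  r^2 = %s, residual SD = %s\n  SE(slope) = %s, SE(intercept) = %s\n",
              signif(x$r_squared, digits), signif(x$residual_sd, digits),
              signif(x$se_slope, 3), signif(x$se_intercept, 3)))
  invisible(x)
}

#' @export
coef.lv_ols <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.lv_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit))
  if (is.numeric(newdata))
    newdata <- stats::setNames(data.frame(newdata), object$predictor)
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.lv_ols <- function(object, ...) stats::residuals(object$fit)

#' Scatter-and-fit plot of an OLS remodelling fit
#'
#' MI animals as filled circles with the fitted line; when sham animals are
#' present in the cohort their mean is drawn as an open square reference
#' point.
#'
#' @param x An `lv_ols` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.lv_ols <- function(x, ...) {
  d <- x$fit$model
  graphics::plot(d[[x$predictor]], d[[x$outcome]], pch = 16,
                 xlab = x$predictor, ylab = x$outcome, ...)
  graphics::abline(x$intercept, x$slope)
  if (!is.null(x$sham_mean))
    graphics::points(x$sham_mean[[x$predictor]], x$sham_mean[[x$outcome]],
                     pch = 22, cex = 1.5, bg = "white")
  invisible(x)
}

#' Stepwise forward selection of early predictors
#'
#' Pure forward selection: starting from the intercept-only model, the
#' candidate with the smallest partial-F p-value is entered as long as that
#' p-value is below `entry_alpha`; there is no removal step. Ties break by
#' the declared candidate order. Candidates whose addition leaves the model
#' rank-deficient (e.g. a duplicate of an entered column) are skipped with a
#' warning. Rows are restricted to MI animals with complete cases across the
#' outcome and all candidates, so every step is fitted on the same rows.
#'
#' @param cohort A cohort table.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate predictor columns.
#' @param entry_alpha Entry threshold for the partial-F p-value (default
#'   0.05, the conventional forward-selection default).
#' @return Object of class `lv_stepwise`: `steps` (one row per entered
#'   predictor with `partial_f`, `p`, `r_squared_after`), `selected`, the
#'   final `lm` in `$fit`, and the final coefficients.
#' @export
stepwise_forward <- function(cohort, outcome, candidates,
                             entry_alpha = 0.05) {
  mi <- mi_rows(cohort)
  miss <- setdiff(c(outcome, candidates), names(mi))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  d <- mi[stats::complete.cases(mi[, c(outcome, candidates), drop = FALSE]),
          c(outcome, candidates), drop = FALSE]
  if (nrow(d) < length(candidates) + 2L)
    stop(sprintf("need at least %d complete rows for %d candidates",
                 length(candidates) + 2L, length(candidates)))

  entered <- character(0L)
  steps <- data.frame(step = integer(), variable = character(),
                      partial_f = numeric(), p = numeric(),
                      r_squared_after = numeric())
  current <- stats::lm(stats::reformulate("1", outcome), data = d)
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    best <- NULL
    for (cand in remaining) {     # declared order = deterministic tie-break
      trial <- stats::lm(stats::reformulate(c(entered, cand), outcome),
                         data = d)
      if (anyNA(stats::coef(trial))) {
        warning("skipping rank-deficient candidate '", cand, "'",
                call. = FALSE)
        remaining <- setdiff(remaining, cand)
        next
      }
      an <- stats::anova(current, trial)
      fstat <- an$F[2L]; pval <- an$`Pr(>F)`[2L]
      if (is.null(best) || pval < best$p)
        best <- list(cand = cand, f = fstat, p = pval, fit = trial)
    }
    if (is.null(best) || is.na(best$p) || best$p >= entry_alpha) break
    entered <- c(entered, best$cand)
    remaining <- setdiff(remaining, best$cand)
    current <- best$fit
    steps <- rbind(steps, data.frame(
      step = length(entered), variable = best$cand, partial_f = best$f,
      p = best$p, r_squared_after = summary(current)$r.squared))
  }
  structure(
    list(outcome = outcome, candidates = candidates,
         entry_alpha = entry_alpha, steps = steps, selected = entered,
         coefficients = stats::coef(current), fit = current, n = nrow(d)),
    class = "lv_stepwise")
}

#' @export
print.lv_stepwise <- function(x, ...) {
  cat(sprintf("Stepwise forward selection for %s (entry p < %g, n = %d)\n",
              x$outcome, x$entry_alpha, x$n))
  if (!nrow(x$steps)) {
    cat("  no candidate entered (empty model)\n")
  } else {
    print(x$steps, row.names = FALSE)
    cat("  final model coefficients:\n")
    print(x$coefficients)
  }
  invisible(x)
}

#' @export
coef.lv_stepwise <- function(object, ...) object$coefficients
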