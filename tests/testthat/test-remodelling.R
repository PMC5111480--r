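test_that("pairwise correlations match the direct covariance formula and cor.test", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.1)
  y <- c(10.1, 14.2, 11.9, 21.5, 16.0)
  co <- cohort_scaffold(5)
  co$x <- x; co$y <- y
  tab <- correlation_table(co, "x", "y")
  # brute-force covariance-formula oracle
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tab$r, r_oracle, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(tab$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(tab$p, ct$p.value, tolerance = 1e-12)
  expect_equal(tab$n, 5L)
})

test_that("a perfect linear relation gives r = 1 with vanishing p", {
  co <- cohort_scaffold(10)
  co$y <- 2 * co$lv_esv_wk1 + 7
  tab <- correlation_table(co, "lv_esv_wk1", "y")
  expect_equal(tab$r, 1)
  expect_equal(tab$p, 0)
})

test_that("constant columns raise an error naming the pair", {
  co <- cohort_scaffold(10)
  expect_error(correlation_table(co, "lv_mass_wk1", "lv_edv_wk4"),
               "lv_mass_wk1.*constant|constant.*lv_mass_wk1")
})

test_that("simple-regression r-squared equals the squared Pearson r", {
  sim <- generate_cohort(cohort_spec(seed = 31))
  tab <- correlation_table(sim$cohort, "lv_esv_wk1", "lv_edv_wk4")
  fit <- ols_fit(sim$cohort, "lv_edv_wk4", "lv_esv_wk1")
  expect_equal(fit$r_squared, tab$r^2, tolerance = 1e-12)
})

test_that("OLS interpolates exactly collinear data", {
  co <- cohort_scaffold(3)
  co$lv_edv_wk4 <- 1.5 * co$lv_esv_wk1 + 10
  fit <- suppressWarnings(ols_fit(co, "lv_edv_wk4", "lv_esv_wk1"))
  expect_equal(fit$slope, 1.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 10, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  co$lv_esv_wk1 <- 30
  expect_error(ols_fit(co, "lv_edv_wk4", "lv_esv_wk1"), "constant")
})

test_that("a noise-free cohort from the default remodelling line is recovered exactly", {
  spec <- cohort_spec(
    wk1 = list(esv_sd = 0, sv_sd = 0, mass_sd = 0, is_sd = 0),
    wk4 = list(edv_sd = 0, esv_sd = 0, mass_sd = 0), seed = 99)
  sim <- generate_cohort(spec)
  fit <- suppressWarnings(ols_fit(sim$cohort, "lv_edv_wk4", "lv_esv_wk1"))
  expect_equal(fit$slope, 1.33, tolerance = 1e-9)
  expect_equal(fit$intercept, 26, tolerance = 1e-9)
  # noise-free linked pair correlates perfectly
  expect_equal(correlation_table(sim$cohort, "lv_esv_wk1", "lv_edv_wk4")$r, 1,
               tolerance = 1e-12)
})

test_that("unit rescaling transforms coefficients and leaves r and EF stats alone", {
  sim <- generate_cohort(cohort_spec(seed = 12))
  fit_ul <- ols_fit(sim$cohort, "lv_edv_wk4", "lv_esv_wk1")
  ml <- sim$cohort
  ml$lv_esv_wk1 <- ml$lv_esv_wk1 / 1000   # ul -> ml
  fit_ml <- ols_fit(ml, "lv_edv_wk4", "lv_esv_wk1")
  expect_equal(fit_ml$slope, fit_ul$slope * 1000, tolerance = 1e-9)
  expect_equal(fit_ml$intercept, fit_ul$intercept, tolerance = 1e-9)
  expect_equal(fit_ml$r_squared, fit_ul$r_squared, tolerance = 1e-12)
  expect_equal(correlation_table(ml, "lv_esv_wk1", "lv_edv_wk4")$r,
               correlation_table(sim$cohort, "lv_esv_wk1", "lv_edv_wk4")$r,
               tolerance = 1e-12)
})

test_that("predict/coef/residuals methods are consistent with the line", {
  sim <- generate_cohort(cohort_spec(seed = 8))
  fit <- ols_fit(sim$cohort, "lv_edv_wk4", "lv_esv_wk1")
  expect_equal(unname(coef(fit)), c(fit$intercept, fit$slope))
  expect_equal(unname(predict(fit, 50)), fit$intercept + fit$slope * 50)
  mi <- sim$cohort[sim$cohort$group == "MI", ]
  expect_equal(unname(predict(fit) + residuals(fit)),
               mi$lv_edv_wk4, tolerance = 1e-9)
})

test_that("stepwise with a single candidate reduces to the marginal test", {
  sim <- generate_cohort(cohort_spec(seed = 21))
  sw <- stepwise_forward(sim$cohort, "lv_edv_wk4", "lv_esv_wk1")
  tab <- correlation_table(sim$cohort, "lv_esv_wk1", "lv_edv_wk4")
  expect_identical(sw$selected, "lv_esv_wk1")
  # the partial-F p of the only step equals the Pearson-t p
  expect_equal(sw$steps$p, tab$p, tolerance = 1e-9)
  expect_equal(sw$steps$r_squared_after, tab$r^2, tolerance = 1e-9)
})

test_that("stepwise enters the dominant predictor and r-squared never decreases", {
  sim <- generate_cohort(cohort_spec(seed = 5))
  sw <- stepwise_forward(sim$cohort, "lv_edv_wk4", WK1_PREDICTORS)
  expect_equal(sw$selected[1], "lv_esv_wk1")
  if (nrow(sw$steps) > 1)
    expect_true(all(diff(sw$steps$r_squared_after) >= 0))
})

test_that("a duplicated candidate column is entered only once", {
  sim <- generate_cohort(cohort_spec(seed = 44))
  co <- sim$cohort
  co$esv_copy <- co$lv_esv_wk1
  expect_warning(
    sw <- stepwise_forward(co, "lv_edv_wk4", c("lv_esv_wk1", "esv_copy")),
    "rank-deficient")
  expect_identical(sw$selected, "lv_esv_wk1")
})

test_that("table1 report flags the per-outcome best predictor", {
  sim <- generate_cohort(cohort_spec(seed = 2))
  tab <- table1_report(sim$cohort)
  expect_equal(nrow(tab), 5 * 4)
  expect_equal(sum(tab$best), 4)
  best <- tab[tab$best, ]
  # the generator drives volume and mass outcomes from week-1 ESV
  for (o in c("lv_mass_wk4", "lv_esv_wk4", "lv_edv_wk4"))
    expect_identical(best$predictor[best$outcome == o], "lv_esv_wk1")
  # regenerating the report from the serialised table is the identity
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), csv, row.names = FALSE)
  expect_equal(utils::read.csv(csv)$r, tab$r, tolerance = 1e-12)
})

test_that("independent columns do not produce spuriously strong correlations", {
  set.seed(66)
  co <- cohort_scaffold(25)
  for (v in c(WK1_PREDICTORS, WK4_OUTCOMES))
    co[[v]] <- runif(25, 30, 90)
  tab <- correlation_table(co)
  expect_lt(max(abs(tab$r)), 0.85)
})

test_that("sham animals are excluded from fitting but carried as reference", {
  sim <- generate_cohort(cohort_spec(seed = 13))
  fit <- ols_fit(sim$cohort, "lv_edv_wk4", "lv_esv_wk1")
  expect_equal(fit$n, sum(sim$cohort$group == "MI"))
  expect_false(is.null(fit$sham_mean))
  sham_only <- sim$cohort[sim$cohort$group == "sham", ]
  expect_error(ols_fit(sham_only, "lv_edv_wk4", "lv_esv_wk1"), "no MI rows")
})

test_that("cohort schema violations are named", {
  sim <- generate_cohort(cohort_spec(seed = 1))
  co <- sim$cohort
  co$lv_ef_wk1 <- NULL
  expect_error(validate_cohort(co), "lv_ef_wk1")
  co2 <- sim$cohort
  co2$subject_id[2] <- co2$subject_id[1]
  expect_error(validate_cohort(co2), "duplicated")
  co3 <- sim$cohort
  co3$lv_ef_wk4[1] <- 130
  expect_error(validate_cohort(co3), "lv_ef_wk4")
})
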