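# one slice, two phases; arcs on the larger (ED) polygons unless stated
ring_study <- function(endo_arcs = NULL, epi_arcs = NULL, n = 10,
                       arcs_on_phase = 0L, scale = 1) {
  tr <- list()
  for (p in 0:1) {
    r_en <- if (p == 0) 2 else 1.5
    a_en <- if (p == arcs_on_phase) endo_arcs else NULL
    a_ep <- if (p == arcs_on_phase) epi_arcs else NULL
    tr <- c(tr, list(
      contour_tracing(0, p, "endo", make_regular_polygon(n, r_en * scale), a_en),
      contour_tracing(0, p, "epi", make_regular_polygon(n, 3 * scale), a_ep)))
  }
  cine_study("ring", "week1", tr)
}

test_that("infarct size averages the two border arc fractions", {
  # regular 10-gon: an arc over k+1 vertices spans k of the 10 edges
  st <- ring_study(endo_arcs = rbind(c(0, 4)),   # 3 edges -> I/T = 0.3
                   epi_arcs = rbind(c(0, 5)))    # 4 edges -> I/T = 0.4
  res <- infarct_size(st)
  expect_equal(res$infarct_pct, 100 * (0.4 + 0.3) / 2)
  expect_equal(res$n_slices, 1L)
  expect_equal(res$per_slice$i_en / res$per_slice$t_en, 0.3)
  expect_equal(res$per_slice$i_ep / res$per_slice$t_ep, 0.4)
})

test_that("infarct size is bounded by the no-arc and full-circumference cases", {
  expect_equal(infarct_size(ring_study())$infarct_pct, 0)
  full <- ring_study(endo_arcs = rbind(c(0, 10)), epi_arcs = rbind(c(0, 10)))
  expect_equal(infarct_size(full)$infarct_pct, 100)
})

test_that("arcs marked only away from end-diastole are an error", {
  st <- ring_study(endo_arcs = rbind(c(0, 4)), epi_arcs = rbind(c(0, 5)),
                   arcs_on_phase = 1L)
  expect_error(infarct_size(st), "end-diastolic")
})

test_that("enlarging an arc never decreases the infarct size", {
  last <- -Inf
  for (end in c(3, 5, 7, 9)) {
    st <- ring_study(endo_arcs = rbind(c(0, end)),
                     epi_arcs = rbind(c(0, 5)))
    pct <- infarct_size(st)$infarct_pct
    expect_gte(pct, last)
    last <- pct
  }
})

test_that("disjoint arcs on one border are summed", {
  one <- ring_study(endo_arcs = rbind(c(0, 3), c(5, 8)))   # 2 + 2 edges
  two <- ring_study(endo_arcs = rbind(c(0, 5)))            # 4 edges
  expect_equal(infarct_size(one)$infarct_pct,
               infarct_size(two)$infarct_pct)
})

test_that("infarct size is invariant under uniform spatial scaling", {
  a <- infarct_size(ring_study(endo_arcs = rbind(c(0, 4)),
                               epi_arcs = rbind(c(0, 5))))
  b <- infarct_size(ring_study(endo_arcs = rbind(c(0, 4)),
                               epi_arcs = rbind(c(0, 5)), scale = 3.7))
  expect_equal(a$infarct_pct, b$infarct_pct, tolerance = 1e-12)
})

test_that("a 90-degree akinetic wedge on all slices measures about 25%", {
  ph <- generate_phantom(small_phantom_spec(
    vertices_per_contour = 128,
    infarct = list(theta_start = 20, theta_extent = 90, thinning = 1)))
  res <- infarct_size(ph$study)
  expect_lt(abs(res$infarct_pct - 25), 2)
  expect_equal(res$n_slices, ph$spec$n_slices)
})

test_that("thinned-wedge infarct size matches the dense arc-length oracle", {
  sp <- small_phantom_spec(
    vertices_per_contour = 256,
    infarct = list(theta_start = 20, theta_extent = 90, thinning = 0.5))
  ph <- generate_phantom(sp)
  res <- infarct_size(ph$study)
  # continuous-model oracle, slice by slice, on the end-diastolic borders
  blend <- function(th_deg) {
    half <- sp$infarct$theta_extent / 2
    centre <- sp$infarct$theta_start + half
    d <- abs(((th_deg - centre + 180) %% 360) - 180)
    s <- pmax(-5, pmin(5, half - d))          # 10-degree cosine ramp
    0.5 * (1 + sin(pi * s / 10))
  }
  fracs <- vapply(seq_len(sp$n_slices) - 1L, function(k) {
    z <- (k + 0.5) * sp$slice_thickness
    r0 <- sp$cavity_radius * sqrt(1 - (z / sp$long_axis)^2)
    f_en <- oracle_arc_fraction(function(th) rep(r0, length(th)),
                                sp$infarct$theta_start, sp$infarct$theta_extent)
    r_ep <- function(th) {
      b <- blend(th * 180 / pi)
      b * (r0 + sp$wall_thickness * 0.5) + (1 - b) * (r0 + sp$wall_thickness)
    }
    f_ep <- oracle_arc_fraction(r_ep, sp$infarct$theta_start,
                                sp$infarct$theta_extent)
    (f_en + f_ep) / 2
  }, numeric(1))
  oracle_pct <- 100 * mean(fracs)
  expect_lt(abs(res$infarct_pct - oracle_pct), 1.0)
  # thinning genuinely drags the epicardial fraction below the angular one
  expect_lt(oracle_pct, 25)
})

test_that("restricting NSLICES to infarct-bearing slices rescales the mean", {
  ph <- generate_phantom(small_phantom_spec(
    vertices_per_contour = 128,
    infarct = list(theta_start = 0, theta_extent = 90, thinning = 1,
                   slice_range = c(2L, 4L))))
  all_rule <- infarct_size(ph$study, nslices = "all")
  inf_rule <- infarct_size(ph$study, nslices = "infarcted")
  expect_equal(all_rule$n_slices, 4L)
  expect_equal(inf_rule$n_slices, 2L)
  expect_equal(all_rule$infarct_pct * 4, inf_rule$infarct_pct * 2)
  expect_gt(inf_rule$infarct_pct, all_rule$infarct_pct)
})

test_that("infarct report round-trips and is consistent with the result", {
  ph <- generate_phantom(small_phantom_spec(
    vertices_per_contour = 128,
    infarct = list(theta_start = 20, theta_extent = 90)))
  res <- infarct_size(ph$study)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  df <- infarct_report(res, csv = csv, json = json)
  expect_equal(nrow(df), res$n_slices)
  expect_equal(100 * mean(df$slice_fraction), res$infarct_pct)
  back <- utils::read.csv(csv)
  expect_equal(back$slice_fraction, df$slice_fraction)
  js <- jsonlite::fromJSON(readLines(json))
  expect_equal(js$infarct_pct, res$infarct_pct)
})
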