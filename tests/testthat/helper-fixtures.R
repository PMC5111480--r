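# Shared fixtures and independent oracles for the test suite.

unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

make_square <- function(side, cx = 0, cy = 0) {
  h <- side / 2
  rbind(c(cx - h, cy - h), c(cx + h, cy - h),
        c(cx + h, cy + h), c(cx - h, cy + h))
}

make_regular_polygon <- function(n, r, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# random convex polygon via the convex hull of random points
rand_convex_polygon <- function(k = 12) {
  repeat {
    pts <- cbind(stats::runif(k, -5, 5), stats::runif(k, -5, 5))
    hull <- grDevices::chull(pts)
    if (length(hull) >= 4) return(pts[rev(hull), , drop = FALSE])
  }
}

# brute-force fan triangulation from the first vertex (valid for convex
# polygons): sum of absolute triangle areas
fan_area <- function(v) {
  n <- nrow(v)
  a <- 0
  for (i in 2:(n - 1)) {
    u <- v[i, ] - v[1, ]; w <- v[i + 1, ] - v[1, ]
    a <- a + abs(u[1] * w[2] - u[2] * w[1]) / 2
  }
  a
}

# study with concentric squares: one slice per element of `endo_areas`
# per phase column; epi area = endo area + wall_area (exact arithmetic)
square_study <- function(endo_areas_by_phase, wall_area = 40,
                         slice_thickness = 1, subject_id = "sq",
                         timepoint = "week1", arcs = NULL) {
  n_phase <- ncol(endo_areas_by_phase)
  n_slice <- nrow(endo_areas_by_phase)
  tr <- list()
  for (s in seq_len(n_slice)) for (p in seq_len(n_phase)) {
    a_en <- endo_areas_by_phase[s, p]
    tr <- c(tr, list(
      contour_tracing(s - 1L, p - 1L, "endocardial",
                      make_square(sqrt(a_en)), arcs),
      contour_tracing(s - 1L, p - 1L, "epicardial",
                      make_square(sqrt(a_en + wall_area)))))
  }
  cine_study(subject_id, timepoint, tr, slice_thickness = slice_thickness)
}

# quadrature oracle: cavity volume of the continuous half-ellipsoid over the
# covered extent, by adaptive 1-D integration along the long axis
oracle_cavity_volume <- function(cavity_radius, long_axis, covered_length,
                                 radial_scale = 1) {
  f <- function(z) pi * (radial_scale * cavity_radius)^2 *
    pmax(0, 1 - (z / long_axis)^2)
  stats::integrate(f, 0, covered_length, rel.tol = 1e-10)$value
}

# brute-force arc-fraction oracle: per-slice wedge arc length over full
# perimeter of the continuous end-diastolic border, via dense polyline
# rasterisation of the polar curve r(theta)
oracle_arc_fraction <- function(r_fun, theta_start, theta_extent,
                                n_dense = 20000) {
  th <- seq(0, 2 * pi, length.out = n_dense + 1)
  r <- r_fun(th)
  xy <- cbind(r * cos(th), r * sin(th))
  seg <- sqrt(rowSums(diff(xy)^2))
  mid_deg <- ((th[-1] + th[-length(th)]) / 2) * 180 / pi
  rel <- (mid_deg - theta_start) %% 360
  in_wedge <- rel <= theta_extent
  sum(seg[in_wedge]) / sum(seg)
}

# small, fast phantom for tests that do not probe discretisation accuracy
small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(n_slices = 4, n_phases = 8, vertices_per_contour = 64), list(...))
  do.call(phantom_spec, args)
}

# valid 25-animal MI cohort scaffold whose measurement columns can be
# overwritten with arbitrary test columns
cohort_scaffold <- function(n = 25) {
  data.frame(subject_id = sprintf("m%02d", seq_len(n)), group = "MI",
             lv_mass_wk1 = 100, lv_edv_wk1 = 60, lv_esv_wk1 = seq_len(n) + 20,
             lv_ef_wk1 = 50, is_wk1 = 30, lv_mass_wk4 = 120,
             lv_esv_wk4 = 40, lv_edv_wk4 = seq_len(n) + 50, lv_ef_wk4 = 40)
}
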