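#' Specification of the synthetic cine LV phantom
#'
#' The phantom models the left ventricle as a truncated half-ellipsoid
#' cavity surrounded by a myocardial shell, sliced perpendicular to the long
#' axis into contiguous short-axis slices, and contracted radially over the
#' cardiac cycle by a smooth periodic profile. Outside any infarct sector
#' the wall thickens in systole so that the shell cross-section area of each
#' slice is conserved exactly, which makes the end-diastolic and
#' end-systolic mass estimates agree by construction. An optional infarct
#' wedge is thinned (wall thickness scaled by `thinning`) and akinetic (the
#' endocardial radius in the wedge is frozen at its end-diastolic value);
#' the transition between infarcted and healthy sectors is smoothed over
#' `transition_deg` degrees to keep the polygons simple.
#'
#' @param cavity_radius Equatorial semi-axis of the cavity at end-diastole,
#'   mm (default 2, a typical mouse LV).
#' @param long_axis Long-axis semi-axis of the cavity, mm (default 7).
#' @param wall_thickness In-plane wall thickness at end-diastole, mm
#'   (default 1).
#' @param n_slices Number of contiguous short-axis slices (default 7).
#' @param slice_thickness Slice thickness, mm (default 1).
#' @param n_phases Cardiac phases per cycle (default 20).
#' @param contraction_fraction Peak fractional radial contraction of the
#'   cavity, in (0, 1); the default 0.37 yields an ejection fraction near
#'   60%, typical of a healthy mouse.
#' @param contraction_profile Smooth periodic function of cycle fraction
#'   `t` in `[0, 1)` returning the relative contraction in `[0, 1]`; the
#'   default `(1 - cos(2*pi*t))/2` starts at end-diastole (phase 0) and
#'   peaks mid-cycle.
#' @param infarct `NULL` or a list with `theta_start` and `theta_extent`
#'   (degrees), optional `slice_range` (0-based half-open, default all
#'   slices), `thinning` in (0, 1] (default 0.6) and logical `akinetic`
#'   (default `TRUE`).
#' @param vertices_per_contour Polygon vertices per border (default 96).
#' @param observer_noise_sd SD of Gaussian tracing noise per vertex
#'   coordinate, mm (default 0: noise-free geometry).
#' @param transition_deg Angular width of the infarct-to-healthy smoothing
#'   ramp, degrees (default 10).
#' @param subject_id,timepoint Labels for the emitted study.
#' @param seed Integer seed for the tracing-noise stream (default 1).
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(cavity_radius = 2, long_axis = 7, wall_thickness = 1,
                         n_slices = 7, slice_thickness = 1, n_phases = 20,
                         contraction_fraction = 0.37,
                         contraction_profile = function(t) (1 - cos(2 * pi * t)) / 2,
                         infarct = NULL, vertices_per_contour = 96,
                         observer_noise_sd = 0, transition_deg = 10,
                         subject_id = "phantom01", timepoint = "week1",
                         seed = 1L) {
  stopifnot(cavity_radius > 0, long_axis > 0, wall_thickness > 0,
            n_slices >= 1, slice_thickness > 0, n_phases >= 2,
            contraction_fraction > 0, contraction_fraction < 1,
            vertices_per_contour >= 8, observer_noise_sd >= 0,
            transition_deg >= 0)
  if ((n_slices - 0.5) * slice_thickness >= long_axis)
    stop("slice stack extends beyond the long axis; reduce n_slices or slice_thickness")
  if (!is.null(infarct)) {
    infarct <- utils::modifyList(
      list(theta_start = 20, theta_extent = 90,
           slice_range = c(0L, n_slices), thinning = 0.6, akinetic = TRUE),
      infarct)
    if (infarct$theta_extent < 0 || infarct$theta_extent > 360)
      stop("infarct theta_extent must lie in [0, 360] degrees")
    if (infarct$thinning <= 0 || infarct$thinning > 1)
      stop("infarct thinning must lie in (0, 1]: the wall cannot vanish")
    if (infarct$slice_range[1L] < 0 || infarct$slice_range[2L] > n_slices ||
        infarct$slice_range[1L] >= infarct$slice_range[2L])
      stop("infarct slice_range must be a non-empty half-open range within the stack")
  }
  structure(
    list(cavity_radius = cavity_radius, long_axis = long_axis,
         wall_thickness = wall_thickness, n_slices = as.integer(n_slices),
         slice_thickness = slice_thickness, n_phases = as.integer(n_phases),
         contraction_fraction = contraction_fraction,
         contraction_profile = contraction_profile, infarct = infarct,
         vertices_per_contour = as.integer(vertices_per_contour),
         observer_noise_sd = observer_noise_sd,
         transition_deg = transition_deg, subject_id = subject_id,
         timepoint = timepoint, seed = as.integer(seed)),
    class = "phantom_spec")
}

# endocardial cavity radius of the continuous model, mm, at depth z (mm)
phantom_r_en0 <- function(spec, z) {
  spec$cavity_radius * sqrt(pmax(0, 1 - (z / spec$long_axis)^2))
}

# angular blend weight of the infarct sector: 1 inside the wedge, 0 outside,
# cosine-smoothed over `transition_deg` centred on each wedge edge
infarct_blend <- function(theta_deg, infarct, transition_deg) {
  if (is.null(infarct)) return(rep(0, length(theta_deg)))
  half_ext <- infarct$theta_extent / 2
  centre <- infarct$theta_start + half_ext
  d <- abs(((theta_deg - centre + 180) %% 360) - 180)   # angular distance to centre
  s <- half_ext - d                                     # signed distance into wedge
  if (transition_deg <= 0) return(as.numeric(s >= 0))
  tr <- transition_deg
  b <- 0.5 * (1 + sin(pi * pmax(-tr / 2, pmin(tr / 2, s)) / tr))
  b
}

#' Generate a synthetic cine LV study with analytic ground truth
#'
#' Emits a full [cine_study()] (every slice, phase and border) from a
#' [phantom_spec()], together with a ground-truth record holding the
#' analytic end-diastolic and end-systolic cavity volumes over the covered
#' slice extent, the ejection fraction, the shell (myocardial) volume and
#' mass at end-diastole, the true ED/ES phases, and the infarct angular
#' fraction. The emitted contour coordinates are rounded to 1e-6 mm, the
#' precision of the contour file dialect, so a write/read round trip is the
#' identity. Generation is fully reproducible from the spec seed.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `lv_phantom` with elements `study`, `truth`, `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_phases = 6, vertices_per_contour = 48))
#' ph$truth$edv_ul
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$vertices_per_contour
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  theta_deg <- theta * 180 / pi
  dz <- spec$slice_thickness
  cf <- spec$contraction_fraction
  w <- spec$wall_thickness
  phases <- seq.int(0L, spec$n_phases - 1L)
  contraction <- cf * vapply(phases / spec$n_phases, spec$contraction_profile,
                             numeric(1L))

  inf <- spec$infarct
  blend0 <- infarct_blend(theta_deg, inf, spec$transition_deg)
  flags <- blend0 >= 0.5

  tracings <- vector("list", 2L * spec$n_slices * spec$n_phases)
  k <- 0L
  for (s in seq.int(0L, spec$n_slices - 1L)) {
    z <- (s + 0.5) * dz
    r_en0 <- phantom_r_en0(spec, z)
    if (r_en0 <= 0) stop("cavity radius vanished inside the slice stack")
    r_ep0 <- r_en0 + w
    delta <- r_ep0^2 - r_en0^2              # conserved shell ring area / pi
    in_inf_slice <- !is.null(inf) && s >= inf$slice_range[1L] &&
      s < inf$slice_range[2L]
    blend <- if (in_inf_slice) blend0 else rep(0, n)
    arcs <- if (in_inf_slice && any(flags)) arcs_from_flags(as.integer(flags))
            else NULL
    for (p in phases) {
      c_p <- contraction[p + 1L]
      rh_en <- r_en0 * (1 - c_p)            # healthy contracted cavity radius
      rh_ep <- sqrt(rh_en^2 + delta)        # shell-area-conserving epicardium
      if (in_inf_slice) {
        ri_en <- if (isTRUE(inf$akinetic)) r_en0 else rh_en
        ri_ep <- ri_en + w * inf$thinning   # thinned, non-thickening wall
        r_en <- blend * ri_en + (1 - blend) * rh_en
        r_ep <- blend * ri_ep + (1 - blend) * rh_ep
      } else {
        r_en <- rep(rh_en, n); r_ep <- rep(rh_ep, n)
      }
      for (border in c("epicardial", "endocardial")) {
        r <- if (border == "epicardial") r_ep else r_en
        v0 <- cbind(r * cos(theta), r * sin(theta))
        k <- k + 1L
        tracings[[k]] <- noisy_tracing(s, p, border, v0, arcs,
                                       spec$observer_noise_sd)
      }
    }
  }
  study <- cine_study(spec$subject_id, spec$timepoint, tracings,
                      slice_thickness = dz)

  truth <- phantom_truth(spec, contraction)
  structure(list(study = study, truth = truth, spec = spec),
            class = "lv_phantom")
}

# tracing noise emulates imperfect manual tracing; re-jitter if the noise
# happens to break polygon simplicity
noisy_tracing <- function(s, p, border, v0, arcs, noise_sd, max_retry = 20L) {
  if (noise_sd == 0)
    return(contour_tracing(s, p, border, round(v0, 6L), arcs))
  for (i in seq_len(max_retry)) {
    v <- round(v0 + matrix(stats::rnorm(length(v0), sd = noise_sd),
                           ncol = 2L), 6L)
    tr <- tryCatch(contour_tracing(s, p, border, v, arcs),
                   error = function(e) NULL)
    if (!is.null(tr)) return(tr)
  }
  stop("observer_noise_sd too large for the contour vertex spacing")
}

# Analytic ground truth of the continuous phantom over the covered extent
# [0, n_slices * dz]. EDV and the no-infarct ESV/shell have closed forms;
# with an infarct the ES cavity and the thinned ED shell are integrated on a
# dense grid of the continuous model (independent of the emitted polygons).
phantom_truth <- function(spec, contraction) {
  L <- spec$n_slices * spec$slice_thickness
  a <- spec$cavity_radius; al <- spec$long_axis; w <- spec$wall_thickness
  edv <- pi * a^2 * (L - L^3 / (3 * al^2))
  es_phase <- which.max(contraction) - 1L
  ed_phase <- which.min(contraction) - 1L
  cmax <- max(contraction)
  inf <- spec$infarct

  int_r <- stats::integrate(function(z) phantom_r_en0(spec, z), 0, L,
                            rel.tol = 1e-10)$value
  if (is.null(inf)) {
    esv <- edv * (1 - cmax)^2
    shell <- pi * (2 * w * int_r + w^2 * L)   # integral of pi((r+w)^2 - r^2)
  } else {
    grid <- phantom_grid_volumes(spec, cmax)
    esv <- grid$esv; shell <- grid$shell_ed
  }
  list(edv_ul = edv, esv_ul = esv, sv_ul = edv - esv,
       ef_pct = (edv - esv) / edv * 100,
       shell_volume_mm3 = shell,
       mass_mg = shell * MYOCARDIAL_SPECIFIC_GRAVITY,
       ed_phase = ed_phase, es_phase = es_phase,
       covered_length_mm = L,
       infarct_angular_fraction =
         if (is.null(inf)) 0 else inf$theta_extent / 360)
}

phantom_grid_volumes <- function(spec, cmax, n_theta = 1440L, n_z = 400L) {
  inf <- spec$infarct
  theta_deg <- (seq_len(n_theta) - 0.5) / n_theta * 360
  dz <- spec$n_slices * spec$slice_thickness / n_z
  z <- (seq_len(n_z) - 0.5) * dz
  blend <- infarct_blend(theta_deg, inf, spec$transition_deg)
  z_lo <- inf$slice_range[1L] * spec$slice_thickness
  z_hi <- inf$slice_range[2L] * spec$slice_thickness
  w <- spec$wall_thickness
  esv <- 0; shell_ed <- 0
  for (zi in z) {
    r0 <- phantom_r_en0(spec, zi)
    in_range <- zi >= z_lo && zi < z_hi
    b <- if (in_range) blend else rep(0, n_theta)
    rh <- r0 * (1 - cmax)
    ri <- if (isTRUE(inf$akinetic)) r0 else rh
    r_es <- b * ri + (1 - b) * rh
    esv <- esv + mean(r_es^2) / 2 * 2 * pi * dz
    # ED shell: healthy thickness w, infarct thickness w * thinning
    r_ep_ed <- b * (r0 + w * inf$thinning) + (1 - b) * (r0 + w)
    shell_ed <- shell_ed + mean(r_ep_ed^2 - r0^2) / 2 * 2 * pi * dz
  }
  list(esv = esv, shell_ed = shell_ed)
}

#' @export
print.lv_phantom <- function(x, ...) {
  cat(sprintf("<lv_phantom> %d slices x %d phases, %d vertices/contour%s\n",
              x$spec$n_slices, x$spec$n_phases, x$spec$vertices_per_contour,
              if (is.null(x$spec$infarct)) "" else
                sprintf(", infarct wedge %g deg", x$spec$infarct$theta_extent)))
  cat(sprintf("  truth: EDV %.2f ul, ESV %.2f ul, EF %.1f %%, mass %.1f mg\n",
              x$truth$edv_ul, x$truth$esv_ul, x$truth$ef_pct, x$truth$mass_mg))
  invisible(x)
}

#' Simulate an independent second observer
#'
#' Returns a copy of a cine study with independent Gaussian jitter added to
#' every vertex coordinate, emulating a second investigator re-tracing the
#' same images. Each jittered polygon is re-validated; if jitter breaks
#' polygon simplicity the tracing is re-jittered up to `max_retry` times
#' before failing.
#'
#' @param study A [cine_study()].
#' @param jitter_sd Jitter SD per coordinate, mm.
#' @param seed Optional integer seed for reproducible jitter.
#' @param max_retry Retries per tracing on a validity violation.
#' @return A new, validated [cine_study()].
#' @export
simulate_second_observer <- function(study, jitter_sd, seed = NULL,
                                     max_retry = 20L) {
  stopifnot(inherits(study, "cine_study"), jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (jitter_sd == 0) return(study)
  jittered <- lapply(study$tracings, function(tr) {
    for (i in seq_len(max_retry)) {
      v <- round(tr$vertices +
                   matrix(stats::rnorm(length(tr$vertices), sd = jitter_sd),
                          ncol = 2L), 6L)
      ok <- tryCatch({ validate_polygon(v); TRUE },
                     error = function(e) FALSE)
      if (ok)
        return(contour_tracing(tr$slice_index, tr$phase_index, tr$border, v,
                               tr$infarct_arcs))
    }
    stop("jitter too large: could not produce a valid polygon after ",
         max_retry, " retries")
  })
  tryCatch(
    cine_study(paste0(study$subject_id, "_obs2"), study$timepoint,
               unname(jittered), slice_thickness = study$slice_thickness),
    error = function(e)
      stop("jitter too large: jittered study violates pairing invariants (",
           conditionMessage(e), ")"))
}
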