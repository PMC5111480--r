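#' Planar polygon area (shoelace formula)
#'
#' Absolute, orientation-independent area of a simple closed polygon given as
#' an ordered vertex list. The polygon is implicitly closed: the last vertex
#' connects back to the first and the first vertex is never repeated.
#'
#' @param vertices Two-column numeric matrix (or data frame) of x/y
#'   coordinates in mm, one row per vertex, at least 3 rows.
#' @param check Validate the polygon (simplicity, duplicates) before
#'   computing. Disable only for polygons already validated upstream.
#' @return Area in mm^2 (strictly positive for a valid polygon).
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(vertices, check = TRUE) {
  v <- as_vertex_matrix(vertices)
  if (check) validate_polygon(v)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polyline length along a polygon border
#'
#' Sum of Euclidean segment lengths over a half-open vertex index range
#' `[start, end)` of an implicitly closed polygon. The range addresses
#' vertices, so a range holding `k` vertices spans `k - 1` edges; the
#' degenerate empty range has length 0. With `closed = TRUE` and a range
#' covering all vertices, the closing edge (last vertex back to the first)
#' is included, giving the full perimeter.
#'
#' @param vertices Two-column numeric matrix of vertex coordinates (mm).
#' @param index_range Integer vector `c(start, end)`, 0-based half-open;
#'   defaults to the full vertex range.
#' @param closed Include the closing edge when the range covers all
#'   vertices (i.e. return the closed perimeter).
#' @return Length in mm.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' polyline_length(sq, closed = TRUE)      # perimeter, 4
#' polyline_length(sq, c(0, 3))            # first two edges, 2
#' @export
polyline_length <- function(vertices, index_range = NULL, closed = FALSE) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (is.null(index_range)) index_range <- c(0L, n)
  if (length(index_range) != 2L || anyNA(index_range))
    stop("`index_range` must be c(start, end)")
  s <- index_range[1L]; e <- index_range[2L]
  if (s < 0L || e > n || s > e)
    stop(sprintf("index range [%d, %d) out of bounds for %d vertices", s, e, n))
  if (e - s < 2L && !(closed && s == 0L && e == n)) return(0)
  idx <- seq.int(s + 1L, e)           # 1-based rows
  if (closed && s == 0L && e == n) idx <- c(idx, 1L)
  seg <- diff(v[idx, , drop = FALSE])
  sum(sqrt(rowSums(seg^2)))
}

# ---- internal geometry helpers ----------------------------------------------

as_vertex_matrix <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L)
    stop("vertices must be a two-column numeric matrix of (x, y) in mm")
  storage.mode(v) <- "double"
  unname(v)
}

# A polygon is valid when it has >= 3 vertices, no consecutive duplicates
# (including last-to-first across the implicit closure) and no two
# non-adjacent edges intersect.
validate_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3L) stop("degenerate polygon: fewer than 3 vertices")
  if (anyNA(v)) stop("polygon vertices contain NA")
  nxt <- c(2:n, 1L)
  dup <- rowSums((v[nxt, , drop = FALSE] - v)^2) == 0
  if (any(dup)) stop("consecutive duplicate vertices are forbidden")
  if (!is_simple_polygon(v)) stop("invalid polygon: self-intersection detected")
  invisible(TRUE)
}

# Vectorised all-pairs proper-intersection test over the n closed edges,
# skipping adjacent edge pairs (which share an endpoint by construction).
is_simple_polygon <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  p <- v; q <- v[nxt, , drop = FALSE]        # edge i: p[i] -> q[i]
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  adj <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(TRUE)
  d1 <- cross2(q[i, ] - p[i, ], p[j, ] - p[i, ])
  d2 <- cross2(q[i, ] - p[i, ], q[j, ] - p[i, ])
  d3 <- cross2(q[j, ] - p[j, ], p[i, ] - p[j, ])
  d4 <- cross2(q[j, ] - p[j, ], q[i, ] - p[j, ])
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(proper)) return(FALSE)
  # collinear overlap / touching interior points
  touch <- (d1 == 0 & on_segment(p[i, ], q[i, ], p[j, ])) |
           (d2 == 0 & on_segment(p[i, ], q[i, ], q[j, ])) |
           (d3 == 0 & on_segment(p[j, ], q[j, ], p[i, ])) |
           (d4 == 0 & on_segment(p[j, ], q[j, ], q[i, ]))
  !any(touch)
}

cross2 <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
}

on_segment <- function(a, b, p) {
  a <- rbind(a); b <- rbind(b); p <- rbind(p)
  (pmin(a[, 1L], b[, 1L]) <= p[, 1L]) & (p[, 1L] <= pmax(a[, 1L], b[, 1L])) &
  (pmin(a[, 2L], b[, 2L]) <= p[, 2L]) & (p[, 2L] <= pmax(a[, 2L], b[, 2L]))
}

# ---- domain types ------------------------------------------------------------

#' Single-border contour tracing
#'
#' One manually traced border (epicardial or endocardial) on one short-axis
#' slice at one cardiac phase, as an ordered planar polygon in mm. The polygon
#' is implicitly closed. Akinetic (infarcted) wall segments are carried as
#' half-open vertex-index ranges on the same polygon, so an arc length can
#' never exceed the circumference it is compared against.
#'
#' @param slice_index 0-based slice index, base to apex.
#' @param phase_index 0-based cardiac phase index.
#' @param border `"epicardial"` or `"endocardial"` (abbreviations
#'   `"epi"`/`"endo"` accepted).
#' @param vertices Two-column numeric matrix of (x, y) in mm, >= 3 rows,
#'   simple and free of consecutive duplicates.
#' @param infarct_arcs Optional integer matrix with columns `start`, `end`:
#'   0-based half-open vertex index ranges marking akinetic segments.
#'   Ranges must lie within `[0, n_vertices]` and must not overlap.
#' @return An object of class `contour_tracing`.
#' @export
contour_tracing <- function(slice_index, phase_index, border, vertices,
                            infarct_arcs = NULL) {
  border <- match.arg(border, c("epicardial", "endocardial", "epi", "endo"))
  border <- switch(border, epi = "epicardial", endo = "endocardial", border)
  v <- as_vertex_matrix(vertices)
  validate_polygon(v)
  if (slice_index < 0 || phase_index < 0)
    stop("slice and phase indices are 0-based and must be non-negative")
  arcs <- validate_arcs(infarct_arcs, nrow(v))
  structure(
    list(slice_index = as.integer(slice_index),
         phase_index = as.integer(phase_index),
         border = border, vertices = v, infarct_arcs = arcs),
    class = "contour_tracing")
}

validate_arcs <- function(arcs, n_vertices) {
  if (is.null(arcs) || NROW(arcs) == 0L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  arcs <- matrix(as.integer(as.matrix(arcs)), ncol = 2L,
                 dimnames = list(NULL, c("start", "end")))
  if (anyNA(arcs)) stop("infarct arcs contain NA indices")
  if (any(arcs[, 1L] < 0L) || any(arcs[, 2L] > n_vertices) ||
      any(arcs[, 1L] >= arcs[, 2L]))
    stop("infarct arc ranges must be non-empty half-open ranges within [0, n_vertices]")
  arcs <- arcs[order(arcs[, 1L]), , drop = FALSE]
  if (nrow(arcs) > 1L && any(arcs[-1L, 1L] < arcs[-nrow(arcs), 2L]))
    stop("infarct arcs must not overlap")
  arcs
}

#' @export
print.contour_tracing <- function(x, ...) {
  cat(sprintf("<contour_tracing> slice %d, phase %d, %s: %d vertices, %d infarct arc(s)\n",
              x$slice_index, x$phase_index, x$border, nrow(x$vertices),
              nrow(x$infarct_arcs)))
  invisible(x)
}

#' Cine study: all tracings for one animal at one timepoint
#'
#' Bundles every contour tracing of one short-axis cine acquisition together
#' with the slice thickness. Construction enforces the pairing invariants:
#' every traced (slice, phase) carries both an epicardial and an endocardial
#' border with the endocardial area strictly smaller; the phase set is
#' identical on every slice; slice indices are contiguous.
#'
#' @param subject_id Animal identifier.
#' @param timepoint `"week1"`, `"week4"`, or any other label.
#' @param tracings List of [contour_tracing()] objects.
#' @param slice_thickness Slice thickness in mm (> 0); default 1.
#' @return An object of class `cine_study`.
#' @export
cine_study <- function(subject_id, timepoint, tracings, slice_thickness = 1) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stop("subject_id must be a non-empty string")
  timepoint <- as.character(timepoint)
  if (!is.numeric(slice_thickness) || length(slice_thickness) != 1L ||
      !is.finite(slice_thickness) || slice_thickness <= 0)
    stop("slice_thickness must be a positive number of mm")
  if (!length(tracings)) stop("a cine study must contain at least one tracing")
  if (!all(vapply(tracings, inherits, logical(1L), "contour_tracing")))
    stop("tracings must be a list of contour_tracing objects")

  key <- vapply(tracings, function(tr)
    paste(tr$slice_index, tr$phase_index, tr$border, sep = "/"), character(1L))
  if (anyDuplicated(key)) stop("duplicate tracing for a (slice, phase, border)")
  names(tracings) <- key

  sl <- vapply(tracings, `[[`, integer(1L), "slice_index")
  ph <- vapply(tracings, `[[`, integer(1L), "phase_index")
  bd <- vapply(tracings, `[[`, character(1L), "border")

  slices <- sort(unique(sl))
  if (!identical(slices, seq.int(min(slices), max(slices))))
    stop("slice indices must be contiguous (a missing interior slice corrupts the Simpson sum)")
  phase_ref <- sort(unique(ph[sl == slices[1L]]))
  for (s in slices) {
    if (!identical(sort(unique(ph[sl == s])), phase_ref))
      stop(sprintf("slice %d does not carry the same phase set as slice %d", s, slices[1L]))
    for (p in phase_ref) {
      here <- bd[sl == s & ph == p]
      if (!all(c("epicardial", "endocardial") %in% here))
        stop(sprintf("missing paired border for slice %d, phase %d", s, p))
    }
  }

  obj <- structure(
    list(subject_id = subject_id, timepoint = timepoint,
         slice_thickness = slice_thickness, tracings = tracings,
         slices = slices, phases = phase_ref),
    class = "cine_study")

  # containment proxy: endocardial area strictly inside the epicardial border
  for (s in slices) for (p in phase_ref) {
    a_epi <- polygon_area(get_tracing(obj, s, p, "epicardial")$vertices, check = FALSE)
    a_endo <- polygon_area(get_tracing(obj, s, p, "endocardial")$vertices, check = FALSE)
    if (a_endo >= a_epi)
      stop(sprintf(
        "endocardial area (%.3f mm^2) must be smaller than epicardial area (%.3f mm^2) at slice %d, phase %d",
        a_endo, a_epi, s, p))
  }
  obj
}

#' Look up one tracing of a cine study
#' @param study A [cine_study()].
#' @param slice,phase 0-based indices.
#' @param border `"epicardial"` or `"endocardial"`.
#' @return The matching [contour_tracing()].
#' @export
get_tracing <- function(study, slice, phase, border) {
  tr <- study$tracings[[paste(slice, phase, border, sep = "/")]]
  if (is.null(tr))
    stop(sprintf("no %s tracing at slice %s, phase %s", border, slice, phase))
  tr
}

#' @export
print.cine_study <- function(x, ...) {
  cat(sprintf("<cine_study> %s @ %s: %d slice(s) x %d phase(s), thickness %g mm\n",
              x$subject_id, x$timepoint, length(x$slices), length(x$phases),
              x$slice_thickness))
  invisible(x)
}

# ---- contour CSV dialect -----------------------------------------------------

CONTOUR_COLUMNS <- c("subject_id", "timepoint", "slice_index", "phase_index",
                     "border", "vertex_index", "x_mm", "y_mm", "infarct")

#' Read a contour CSV file into a cine study
#'
#' The dialect is one row per vertex with mandatory header
#' `subject_id,timepoint,slice_index,phase_index,border,vertex_index,x_mm,y_mm,infarct`,
#' border coded `epi`/`endo`, infarct coded 0/1, '.' decimal separator, and
#' study-level metadata (slice thickness) in leading comment lines of the form
#' `# slice_thickness_mm=<value>`. Infarct arcs are reconstructed as maximal
#' runs of `infarct = 1` vertices. All study invariants are enforced on load.
#'
#' @param path Path to a contour CSV file.
#' @return A validated [cine_study()].
#' @seealso [write_contours()]
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- parse_meta(lines[is_meta])
  body <- lines[!is_meta]
  if (!length(body)) stop("contour file has no data rows: ", path)
  df <- tryCatch(
    utils::read.csv(text = body, colClasses = c(
      subject_id = "character", timepoint = "character",
      slice_index = "integer", phase_index = "integer", border = "character",
      vertex_index = "integer", x_mm = "numeric", y_mm = "numeric",
      infarct = "integer")),
    error = function(e) stop("malformed contour CSV: ", conditionMessage(e)))
  if (!identical(names(df), CONTOUR_COLUMNS))
    stop("contour CSV header must be exactly: ", paste(CONTOUR_COLUMNS, collapse = ","))

  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    line_no <- which(!is_meta)[1L] + bad[1L]  # +1 for header within body
    stop(sprintf("malformed row at line %d of %s", line_no, path))
  }
  if (!all(df$border %in% c("epi", "endo")))
    stop("border column must be 'epi' or 'endo'")
  if (!all(df$infarct %in% c(0L, 1L)))
    stop("infarct column must be 0 or 1")
  if (length(unique(df$subject_id)) != 1L || length(unique(df$timepoint)) != 1L)
    stop("a contour file must hold exactly one subject at one timepoint")

  thick <- meta[["slice_thickness_mm"]]
  if (is.null(thick)) thick <- 1
  groups <- split(df, list(df$slice_index, df$phase_index, df$border), drop = TRUE)
  tracings <- lapply(groups, function(g) {
    g <- g[order(g$vertex_index), , drop = FALSE]
    if (!identical(g$vertex_index, seq.int(0L, nrow(g) - 1L)))
      stop(sprintf("vertex indices of slice %d, phase %d, %s are not 0..n-1",
                   g$slice_index[1L], g$phase_index[1L], g$border[1L]))
    contour_tracing(g$slice_index[1L], g$phase_index[1L], g$border[1L],
                    cbind(g$x_mm, g$y_mm), arcs_from_flags(g$infarct))
  })
  cine_study(df$subject_id[1L], df$timepoint[1L], unname(tracings),
             slice_thickness = as.numeric(thick))
}

parse_meta <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  out <- list()
  for (p in kv) if (length(p) == 2L) out[[trimws(p[1L])]] <- trimws(p[2L])
  out
}

arcs_from_flags <- function(flags) {
  if (!any(flags == 1L)) return(NULL)
  r <- rle(flags == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values] - 1L, end = ends[r$values])  # 0-based half-open
}

#' Write a cine study to the contour CSV dialect
#'
#' Emits a deterministic, canonical serialisation: one metadata comment line
#' with the slice thickness, then one row per vertex sorted by
#' (slice, phase, border, vertex index), coordinates fixed at 6 decimals.
#' Re-writing a freshly loaded file reproduces it byte for byte.
#'
#' @param study A [cine_study()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(study, path) {
  stopifnot(inherits(study, "cine_study"))
  rows <- lapply(study$tracings, function(tr) {
    n <- nrow(tr$vertices)
    flags <- integer(n)
    if (nrow(tr$infarct_arcs))
      for (k in seq_len(nrow(tr$infarct_arcs)))
        flags[seq.int(tr$infarct_arcs[k, 1L] + 1L, tr$infarct_arcs[k, 2L])] <- 1L
    data.frame(subject_id = study$subject_id, timepoint = study$timepoint,
               slice_index = tr$slice_index, phase_index = tr$phase_index,
               border = if (tr$border == "epicardial") "epi" else "endo",
               vertex_index = seq.int(0L, n - 1L),
               x_mm = tr$vertices[, 1L], y_mm = tr$vertices[, 2L],
               infarct = flags)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$slice_index, df$phase_index, df$border, df$vertex_index), ]
  txt <- sprintf("%s,%s,%d,%d,%s,%d,%.6f,%.6f,%d",
                 df$subject_id, df$timepoint, df$slice_index, df$phase_index,
                 df$border, df$vertex_index, df$x_mm, df$y_mm, df$infarct)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# slice_thickness_mm=%.6f", study$slice_thickness),
               paste(CONTOUR_COLUMNS, collapse = ","), txt), con)
  invisible(path)
}
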