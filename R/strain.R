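# From tracked displacements to the scalar stiffness surrogate: the
# per-frame area-weighted mean tensile principal Green strain, its cycle
# peak, pulse-pressure normalization (% per mmHg), parametric strain
# overlays, and the outer-wall caliper diameter.

#' Per-frame mean principal wall strain curve
#'
#' For every frame, each element's Green-Lagrange strain (evaluated at the
#' element centre, total Lagrangian) is reduced to its larger (tensile)
#' principal value and averaged over the wall with reference-configuration
#' element areas as weights. The curve is zero at the reference frame; its
#' maximum is the peak mean principal strain.
#'
#' @param mesh a [build_quad_mesh()] result.
#' @param disp a `displacement_sequence` from [track_cycle()], or a list of
#'   N x 2 displacement matrices (mm).
#' @param frame_rate_hz optional; fills the `time_s` field.
#' @param measure strain measure, passed to [element_green_strain()].
#' @return object of class `strain_curve`: `values` (per-frame fraction),
#'   `peak_value`, `peak_frame` (0-based, relative to the cycle start),
#'   `time_s`, `per_element` (E x n_frames matrix of element principal
#'   strains).
#' @export
strain_curve <- function(mesh, disp, frame_rate_hz = NULL, measure = "green") {
  frames <- if (inherits(disp, "displacement_sequence")) disp$disp else disp
  areas <- element_areas(mesh)
  per_el <- vapply(frames, function(d) {
    if (nrow(d) != nrow(mesh$nodes))
      stop_ws("displacement/mesh node count mismatch", "shape_error")
    element_principal_strain(mesh, d, measure = measure)
  }, numeric(nrow(mesh$elements)))
  per_el <- matrix(per_el, nrow = nrow(mesh$elements))
  values <- as.vector(crossprod(per_el, areas)) / sum(areas)
  peak_frame <- which.max(values) - 1L
  structure(list(
    values = values,
    peak_value = values[peak_frame + 1L],
    peak_frame = peak_frame,
    time_s = if (!is.null(frame_rate_hz)) (seq_along(values) - 1) / frame_rate_hz else NULL,
    per_element = per_el
  ), class = "strain_curve")
}

#' Identify the diastolic and systolic frames of a strain curve
#'
#' The diastolic frame is the curve minimum and the systolic frame the curve
#' maximum, each resolved to the earliest frame on ties. An all-constant
#' curve returns `c(0, 0)` with a degenerate-cycle warning.
#'
#' @param curve a [strain_curve()] or a numeric vector of per-frame strain.
#' @return integer c(diastolic_frame, systolic_frame), 0-based.
#' @export
select_cycle_extremes <- function(curve) {
  v <- if (inherits(curve, "strain_curve")) curve$values else as.numeric(curve)
  if (!length(v)) stop_ws("empty strain curve", "invalid_input")
  if (diff(range(v)) == 0) {
    warning("degenerate cycle: strain curve is constant")
    return(c(0L, 0L))
  }
  c(which.min(v) - 1L, which.max(v) - 1L)
}

#' Normalize peak strain by pulse pressure
#'
#' The biomarker: `100 * eps_peak / (systolic - diastolic)` in percent per
#' mmHg, using the independently measured brachial cuff pressures.
#'
#' @param eps_peak peak mean principal strain (dimensionless fraction).
#' @param pressure a [pressure_measurement()].
#' @return list with `eps_pp` (%/mmHg) and `pulse_pressure_mmHg`.
#' @export
#' @examples
#' normalize_by_pp(0.02, pressure_measurement(120, 80))$eps_pp  # 0.05
normalize_by_pp <- function(eps_peak, pressure) {
  if (!inherits(pressure, "pressure_measurement"))
    pressure <- pressure_measurement(pressure[[1]], pressure[[2]])
  list(eps_pp = 100 * eps_peak / pressure$pulse_pressure_mmHg,
       pulse_pressure_mmHg = pressure$pulse_pressure_mmHg)
}

#' Parametric strain overlay on a B-mode frame
#'
#' Fills each element polygon with a color mapped from its tensile principal
#' strain and alpha-blends the overlay onto the grayscale frame, the
#' standard way regional wall strain is visualized on cine frames.
#'
#' @param frame grayscale matrix (any range; rescaled to \[0, 1\]).
#' @param mesh a [build_quad_mesh()] result.
#' @param per_element_eps1 numeric vector, length = number of elements.
#' @param pixel_spacing_mm pixel size (mm) used to place the mesh.
#' @param strain_range colormap limits (fractions); values are clamped.
#' @param alpha overlay opacity in \[0, 1\].
#' @return H x W x 3 array in \[0, 1\]; attributes `colormap_range` and
#'   `colormap` describe the color scale.
#' @export
render_parametric_image <- function(frame, mesh, per_element_eps1,
                                    pixel_spacing_mm,
                                    strain_range = c(0, 0.1), alpha = 0.55) {
  E <- nrow(mesh$elements)
  if (length(per_element_eps1) != E)
    stop_ws("per_element_eps1 length must equal the element count", "shape_error")
  H <- nrow(frame); W <- ncol(frame)
  rng <- range(frame)
  g <- if (diff(rng) > 0) (frame - rng[1]) / diff(rng) else frame * 0
  out <- array(rep(g, 3), dim = c(H, W, 3))
  pal <- grDevices::hcl.colors(256, "Viridis")
  t01 <- pmin(pmax((per_element_eps1 - strain_range[1]) /
                     diff(strain_range), 0), 1)
  cols <- grDevices::col2rgb(pal[1 + round(t01 * 255)]) / 255
  xs <- matrix(rep(0:(W - 1), each = H), H, W) * pixel_spacing_mm
  ys <- matrix(rep(0:(H - 1), W), H, W) * pixel_spacing_mm
  for (e in seq_len(E)) {
    poly <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    bb <- cbind(range(poly[, 1]), range(poly[, 2]))
    cand <- which(xs >= bb[1, 1] & xs <= bb[2, 1] &
                    ys >= bb[1, 2] & ys <= bb[2, 2])
    if (!length(cand)) next
    inside <- points_in_polygon(cbind(xs[cand], ys[cand]), poly)
    idx <- cand[inside]
    if (!length(idx)) next
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[idx] <- (1 - alpha) * plane[idx] + alpha * cols[ch, e]
      out[, , ch] <- plane
    }
  }
  attr(out, "colormap_range") <- strain_range
  attr(out, "colormap") <- "Viridis"
  out
}

#' Maximum outer-wall diameter (caliper measurement)
#'
#' The maximum caliper of the outer contour — the largest pairwise vertex
#' distance, found by rotating calipers on the convex hull — measured
#' outer wall to outer wall on the end-diastolic reference frame and
#' reported in cm.
#'
#' @param roi a [wall_roi()], or an n x 2 outer-contour matrix (mm).
#' @return diameter in cm.
#' @export
#' @examples
#' measure_outer_diameter(circle_contour(c(0, 0), 22, 256))  # ~4.4
measure_outer_diameter <- function(roi) {
  pts <- if (inherits(roi, "wall_roi")) roi$outer else as.matrix(roi)
  if (nrow(pts) < 3) stop_ws("outer contour needs at least 3 points", "invalid_contour")
  h <- grDevices::chull(pts)          # convex hull, clockwise order
  hull <- pts[rev(h), , drop = FALSE] # counterclockwise
  m <- nrow(hull)
  if (m == 1) return(0)
  if (m == 2) return(sqrt(sum((hull[1, ] - hull[2, ])^2)) / 10)
  # rotating calipers: walk antipodal vertex pairs
  area2 <- function(a, b, c) abs((b[1] - a[1]) * (c[2] - a[2]) -
                                   (b[2] - a[2]) * (c[1] - a[1]))
  best <- 0
  k <- 2L
  nxt <- function(i) if (i == m) 1L else i + 1L
  for (i in seq_len(m)) {
    j <- nxt(i)
    while (area2(hull[i, ], hull[j, ], hull[nxt(k), ]) >
           area2(hull[i, ], hull[j, ], hull[k, ])) k <- nxt(k)
    best <- max(best,
                sqrt(sum((hull[i, ] - hull[k, ])^2)),
                sqrt(sum((hull[j, ] - hull[k, ])^2)))
  }
  best / 10   # mm -> cm
}
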