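# Four-node quadrilateral finite-element discretization of the wall region
# between the inner and outer contour, and Green-Lagrange strain per element.
#
# Coordinates are image-physical millimetres: origin at the centre of the
# top-left pixel, x increasing rightward, y increasing downward, everything
# 0-based. "Counterclockwise" below means positive shoelace signed area in
# these axes; contours are reoriented on input so element Jacobians come out
# positive.

#' Two-contour wall region of interest
#'
#' @param inner_contour,outer_contour n x 2 matrices of ordered (x, y)
#'   points in mm; closed polygons without a repeated end vertex. The inner
#'   contour must lie strictly inside the outer one.
#' @param reference_frame 0-based index of the end-diastolic frame the
#'   contours were drawn on.
#' @return object of class `wall_roi`.
#' @export
wall_roi <- function(inner_contour, outer_contour, reference_frame = 0L) {
  inner_contour <- as.matrix(inner_contour)
  outer_contour <- as.matrix(outer_contour)
  for (nm in c("inner", "outer")) {
    m <- if (nm == "inner") inner_contour else outer_contour
    if (ncol(m) != 2 || nrow(m) < 3 || !all(is.finite(m)))
      stop_ws(sprintf("%s contour must be a finite n x 2 matrix, n >= 3", nm),
              "invalid_roi")
    if (polygon_self_intersects(m))
      stop_ws(sprintf("%s contour is self-intersecting", nm), "invalid_roi")
  }
  # consistent orientation: positive signed area
  if (polygon_signed_area(inner_contour) < 0)
    inner_contour <- inner_contour[rev(seq_len(nrow(inner_contour))), ]
  if (polygon_signed_area(outer_contour) < 0)
    outer_contour <- outer_contour[rev(seq_len(nrow(outer_contour))), ]
  if (!all(points_in_polygon(inner_contour, outer_contour)))
    stop_ws("inner contour must lie strictly inside the outer contour",
            "invalid_roi")
  if (any(points_in_polygon(outer_contour, inner_contour)))
    stop_ws("outer contour intersects the region enclosed by the inner contour",
            "invalid_roi")
  structure(list(inner = inner_contour, outer = outer_contour,
                 reference_frame = as.integer(reference_frame)),
            class = "wall_roi")
}

#' Regular polygon approximation of a circle (convenience contour builder)
#'
#' @param center_mm c(x, y) in mm.
#' @param radius_mm radius in mm.
#' @param n number of vertices.
#' @return n x 2 matrix.
#' @export
circle_contour <- function(center_mm, radius_mm, n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center_mm[1] + radius_mm * cos(th),
        center_mm[2] + radius_mm * sin(th))
}

# Even-odd ray-casting point-in-polygon (vectorized over points).
points_in_polygon <- function(pts, poly) {
  x <- pts[, 1]; y <- pts[, 2]
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# O(n^2) segment-pair test; contours are short so this is cheap.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), ])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]   # skip shared-vertex neighbours
    if (!length(js)) next
    if (any(segments_cross(seg[i, 1:2], seg[i, 3:4],
                           seg[js, 1:2, drop = FALSE], seg[js, 3:4, drop = FALSE])))
      return(TRUE)
  }
  FALSE
}

segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[, 1] - p[1]) * (r[, 2] - p[2]) - (q[, 2] - p[2]) * (r[, 1] - p[1])
  o1 <- d(a1, matrix(a2, nrow(b1), 2, byrow = TRUE), b1)
  o2 <- d(a1, matrix(a2, nrow(b1), 2, byrow = TRUE), b2)
  o3 <- (b2[, 1] - b1[, 1]) * (a1[2] - b1[, 2]) - (b2[, 2] - b1[, 2]) * (a1[1] - b1[, 1])
  o4 <- (b2[, 1] - b1[, 1]) * (a2[2] - b1[, 2]) - (b2[, 2] - b1[, 2]) * (a2[1] - b1[, 1])
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

# Arc-length-uniform resampling of a closed polyline into n points, starting
# at the vertex of maximum x (deterministic start rule; first on ties).
resample_contour <- function(poly, n) {
  start <- which.max(poly[, 1])
  poly <- poly[c(start:nrow(poly), seq_len(start - 1)), , drop = FALSE]
  closed <- rbind(poly, poly[1, ])
  seglen <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  targets <- (seq_len(n) - 1) * total / n
  idx <- findInterval(targets, s, rightmost.closed = TRUE)
  t0 <- (targets - s[idx]) / pmax(seglen[idx], .Machine$double.eps)
  closed[idx, , drop = FALSE] * (1 - t0) + closed[idx + 1, , drop = FALSE] * t0
}

#' Build the quadrilateral wall mesh
#'
#' Resamples each contour to `n_circumferential` arc-length-uniform points
#' (starting at the point of maximum x) and linearly interpolates
#' `n_radial + 1` node layers between the inner and outer contour. Elements
#' are four-node quadrilaterals with counterclockwise node order; every
#' element Jacobian is checked at its centre and at the four Gauss points.
#'
#' @param roi a [wall_roi()].
#' @param n_circumferential circumferential element count (>= 4).
#' @param n_radial radial (through-wall) element count (>= 1).
#' @return object of class `quad_mesh` with `nodes` (N x 2 mm),
#'   `elements` (E x 4, 1-based node indices), `n_circumferential`,
#'   `n_radial`.
#' @export
#' @examples
#' roi <- wall_roi(circle_contour(c(0, 0), 10), circle_contour(c(0, 0), 20))
#' m <- build_quad_mesh(roi, 16, 2)
#' nrow(m$elements)  # 32
build_quad_mesh <- function(roi, n_circumferential, n_radial) {
  if (!inherits(roi, "wall_roi")) stop_ws("roi must be a wall_roi", "invalid_roi")
  if (!is_count(n_circumferential, 4)) stop_ws("n_circumferential must be >= 4", "invalid_input")
  if (!is_count(n_radial, 1)) stop_ws("n_radial must be >= 1", "invalid_input")
  nc <- as.integer(n_circumferential); nr <- as.integer(n_radial)
  inner <- resample_contour(roi$inner, nc)
  outer <- resample_contour(roi$outer, nc)
  layers <- lapply(0:nr, function(l) {
    t <- l / nr
    inner * (1 - t) + outer * t
  })
  nodes <- do.call(rbind, layers)          # layer-major: layer l, point j
  node_id <- function(l, j) l * nc + ((j - 1) %% nc) + 1
  elements <- matrix(0L, nc * nr, 4)
  e <- 0L
  for (l in 0:(nr - 1)) {
    for (j in seq_len(nc)) {
      e <- e + 1L
      elements[e, ] <- c(node_id(l, j), node_id(l + 1, j),
                         node_id(l + 1, j + 1), node_id(l, j + 1))
    }
  }
  mesh <- structure(list(nodes = nodes, elements = elements,
                         n_circumferential = nc, n_radial = nr),
                    class = "quad_mesh")
  jac <- element_jacobians(mesh)
  bad <- which(jac <= 0)
  if (length(bad))
    stop_ws(sprintf("meshing produced inverted element(s): %s",
                    paste(utils::head(bad, 5), collapse = ", ")),
            "meshing_error")
  mesh
}

# Minimum Jacobian determinant per element over centre + 4 Gauss points.
element_jacobians <- function(mesh) {
  g <- 1 / sqrt(3)
  pts <- rbind(c(0, 0), c(-g, -g), c(g, -g), c(g, g), c(-g, g))
  apply(mesh$elements, 1, function(el) {
    X <- mesh$nodes[el, , drop = FALSE]
    min(apply(pts, 1, function(p) {
      dN <- shape_grad_ref(p[1], p[2])
      det(t(dN) %*% X)
    }))
  })
}

# Gradients of the four bilinear shape functions wrt (xi, eta); rows = node.
shape_grad_ref <- function(xi, eta) {
  0.25 * cbind(
    c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
    c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
  )
}

# Shape function values at (xi, eta), length 4.
shape_values <- function(xi, eta) {
  0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
           (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
}

#' Reference-configuration element areas (shoelace)
#'
#' @param mesh a [build_quad_mesh()] result.
#' @return numeric vector of length E (mm^2).
#' @export
element_areas <- function(mesh) {
  apply(mesh$elements, 1, function(el)
    abs(polygon_signed_area(mesh$nodes[el, , drop = FALSE])))
}

#' Green-Lagrange strain of one quadrilateral element
#'
#' Bilinear shape-function gradients evaluated at the element centre give the
#' displacement gradient in the reference configuration; the deformation
#' gradient is `F = I + du/dX` and the returned tensor is
#' `E = (F^T F - I) / 2` (total Lagrangian, rotation invariant). Set
#' `measure = "infinitesimal"` for the small-strain tensor
#' `(du/dX + (du/dX)^T) / 2` instead.
#'
#' @param ref_coords 4 x 2 matrix of reference node coordinates (mm),
#'   counterclockwise.
#' @param displacements 4 x 2 matrix of nodal displacements (mm).
#' @param measure `"green"` (default) or `"infinitesimal"`.
#' @return named numeric vector `c(Exx, Eyy, Exy)` (dimensionless).
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' element_green_strain(sq, cbind(0.1 * sq[, 1], 0))  # Exx = 0.105
element_green_strain <- function(ref_coords, displacements,
                                 measure = c("green", "infinitesimal")) {
  measure <- match.arg(measure)
  dN <- shape_grad_ref(0, 0)                 # 4 x 2
  J <- t(dN) %*% ref_coords                  # 2 x 2, J[i, j] = dX_j / dxi_i
  dj <- det(J)
  if (abs(dj) < 1e-12)
    stop_ws("degenerate element: singular reference Jacobian", "degenerate_element")
  dNdX <- dN %*% solve(t(J))                 # 4 x 2, dN/dX
  H <- t(displacements) %*% dNdX             # 2 x 2, du/dX
  E <- if (measure == "green") {
    FF <- diag(2) + H
    (t(FF) %*% FF - diag(2)) / 2
  } else {
    (H + t(H)) / 2
  }
  c(Exx = E[1, 1], Eyy = E[2, 2], Exy = E[1, 2])
}

#' Principal strains of a 2D symmetric strain tensor
#'
#' Closed-form eigenvalues
#' `(Exx + Eyy)/2 +/- sqrt(((Exx - Eyy)/2)^2 + Exy^2)`, sorted descending.
#'
#' @param E named vector `c(Exx, Eyy, Exy)` or a list of the three
#'   components.
#' @return numeric `c(eps1, eps2)` with `eps1 >= eps2`.
#' @export
principal_strains <- function(E) {
  exx <- E[[1]]; eyy <- E[[2]]; exy <- E[[3]]
  if (!all(is.finite(c(exx, eyy, exy))))
    stop_ws("strain tensor components must be finite", "invalid_input")
  m <- (exx + eyy) / 2
  d <- sqrt(((exx - eyy) / 2)^2 + exy^2)
  c(m + d, m - d)
}

#' Per-element tensile principal Green strain for a nodal displacement field
#'
#' @param mesh a [build_quad_mesh()] result.
#' @param node_disp N x 2 matrix of nodal displacements (mm).
#' @param measure passed to [element_green_strain()].
#' @return numeric vector of length E: the larger principal strain per
#'   element.
#' @export
element_principal_strain <- function(mesh, node_disp, measure = "green") {
  if (nrow(node_disp) != nrow(mesh$nodes))
    stop_ws("node count mismatch between mesh and displacement field", "shape_error")
  vapply(seq_len(nrow(mesh$elements)), function(e) {
    el <- mesh$elements[e, ]
    principal_strains(element_green_strain(mesh$nodes[el, , drop = FALSE],
                                           node_disp[el, , drop = FALSE],
                                           measure = measure))[1]
  }, numeric(1))
}
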