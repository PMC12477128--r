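# Synthetic speckle cine loops of a pulsating thick-walled annulus with
# analytic ground-truth displacement and strain.
#
# Wall kinematics are a plane-strain, area-preserving radial map: a material
# point at reference radius r (inside the wall, a0 <= r <= b0) moves to
#   r'(r, t) = sqrt(r^2 + a(t)^2 - a0^2),   a(t) = a0 + (a_peak - a0) w(t),
# where w(t) in [0, 1] is the normalized pressure waveform. The map conserves
# annulus area (incompressible wall), so the in-plane principal stretches are
# lambda_theta = r'/r (tensile) and lambda_r = r/r' and the larger principal
# Green strain is (1/2)((r'/r)^2 - 1), which admits a closed-form area mean.

#' Brachial cuff pressure measurement
#'
#' @param systolic_mmHg,diastolic_mmHg cuff pressures in mmHg;
#'   `systolic > diastolic > 0` is required so the pulse pressure is positive.
#' @return object of class `pressure_measurement` with fields
#'   `systolic_mmHg`, `diastolic_mmHg`, `pulse_pressure_mmHg`.
#' @export
#' @examples
#' pressure_measurement(120, 80)$pulse_pressure_mmHg  # 40
pressure_measurement <- function(systolic_mmHg, diastolic_mmHg) {
  if (!is.finite(systolic_mmHg) || !is.finite(diastolic_mmHg) ||
      diastolic_mmHg <= 0 || systolic_mmHg <= diastolic_mmHg) {
    stop_ws("pulse pressure must be positive (systolic > diastolic > 0)",
            "invalid_pressure")
  }
  structure(list(
    systolic_mmHg = systolic_mmHg,
    diastolic_mmHg = diastolic_mmHg,
    pulse_pressure_mmHg = systolic_mmHg - diastolic_mmHg
  ), class = "pressure_measurement")
}

#' Phantom specification for the pulsating annulus
#'
#' Defines one cardiac cycle, end-diastole to end-diastole, of a thick-walled
#' annulus imaged as a speckle cine loop. Frames 0 and `n_frames - 1` are both
#' end-diastolic, so the ground-truth displacement there is identically zero.
#'
#' @param inner_radius_mm end-diastolic lumen radius a0 (> 0).
#' @param outer_radius_mm end-diastolic outer wall radius b0 (> a0).
#' @param peak_inner_radius_mm systolic lumen radius a_peak (>= a0).
#' @param n_frames frames in the cycle (>= 8).
#' @param frame_rate_hz acquisition rate; clinical loops use >= 50 fps.
#' @param image_size_px integer c(height, width) in pixels.
#' @param pixel_spacing_mm isotropic pixel size (mm).
#' @param speckle_cell_density scatterers per mm^2.
#' @param noise_sigma additive Gaussian noise sd, in intensity units of the
#'   log-compressed image (which is scaled to approximately \[0, 1\]).
#' @param stiff_sector optional `list(start_deg, end_deg, compliance)`: an
#'   angular span whose radial wall displacement is scaled by
#'   `compliance` in \[0, 1\] (1 reproduces the homogeneous phantom exactly);
#'   the transition is tapered over 10 degrees.
#' @param systolic_fraction cycle fraction at which pressure (and a(t)) peaks.
#' @param seed RNG seed for scatterer placement and noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(inner_radius_mm = 10, outer_radius_mm = 14,
                         peak_inner_radius_mm = 10.5,
                         n_frames = 40L, frame_rate_hz = 50,
                         image_size_px = c(180L, 180L),
                         pixel_spacing_mm = 0.2,
                         speckle_cell_density = 8,
                         noise_sigma = 0.02,
                         stiff_sector = NULL,
                         systolic_fraction = 0.35,
                         seed = 1L) {
  if (inner_radius_mm <= 0 || outer_radius_mm <= inner_radius_mm)
    stop_ws("need 0 < inner_radius_mm < outer_radius_mm", "invalid_spec")
  if (peak_inner_radius_mm < inner_radius_mm)
    stop_ws("peak_inner_radius_mm must be >= inner_radius_mm", "invalid_spec")
  if (!is_count(n_frames, 8)) stop_ws("n_frames must be an integer >= 8", "invalid_spec")
  if (frame_rate_hz <= 0) stop_ws("frame_rate_hz must be positive", "invalid_spec")
  if (length(image_size_px) != 2 || any(image_size_px < 16))
    stop_ws("image_size_px must be c(height, width), both >= 16", "invalid_spec")
  if (pixel_spacing_mm <= 0) stop_ws("pixel_spacing_mm must be positive", "invalid_spec")
  if (speckle_cell_density <= 0) stop_ws("speckle_cell_density must be positive", "invalid_spec")
  if (noise_sigma < 0) stop_ws("noise_sigma must be >= 0", "invalid_spec")
  if (!is.null(stiff_sector)) {
    stopifnot(is.list(stiff_sector),
              all(c("start_deg", "end_deg", "compliance") %in% names(stiff_sector)))
    if (stiff_sector$compliance < 0 || stiff_sector$compliance > 1)
      stop_ws("stiff sector compliance must be in [0, 1]", "invalid_spec")
  }
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop_ws("systolic_fraction must lie strictly inside (0, 1)", "invalid_spec")
  structure(list(
    inner_radius_mm = inner_radius_mm, outer_radius_mm = outer_radius_mm,
    peak_inner_radius_mm = peak_inner_radius_mm,
    n_frames = as.integer(n_frames), frame_rate_hz = frame_rate_hz,
    image_size_px = as.integer(image_size_px),
    pixel_spacing_mm = pixel_spacing_mm,
    speckle_cell_density = speckle_cell_density,
    noise_sigma = noise_sigma, stiff_sector = stiff_sector,
    systolic_fraction = systolic_fraction, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Normalized waveform shape: 0 at t = 0 and t = 1, exactly 1 at t = ts,
# raised-cosine up and down (continuous, unimodal).
waveform_shape <- function(t_frac, ts = 0.35) {
  up <- t_frac <= ts
  w <- numeric(length(t_frac))
  w[up] <- 0.5 * (1 - cos(pi * t_frac[up] / ts))
  w[!up] <- 0.5 * (1 + cos(pi * (t_frac[!up] - ts) / (1 - ts)))
  w
}

#' Intra-cycle pressure waveform
#'
#' Maps a cycle fraction to cuff-calibrated pressure: diastolic at both ends
#' of the cycle, systolic exactly once at `systolic_fraction` (default 0.35),
#' raised-cosine in between (continuous and unimodal).
#'
#' @param t_frac cycle fraction(s) in \[0, 1\].
#' @param pressure a [pressure_measurement()].
#' @param systolic_fraction cycle fraction of peak pressure.
#' @return pressure in mmHg, same length as `t_frac`.
#' @export
#' @examples
#' p <- pressure_measurement(120, 80)
#' pressure_waveform(0, p)      # 80
#' pressure_waveform(0.35, p)   # 120
pressure_waveform <- function(t_frac, pressure, systolic_fraction = 0.35) {
  if (!inherits(pressure, "pressure_measurement"))
    pressure <- pressure_measurement(pressure[[1]], pressure[[2]])
  if (any(t_frac < 0 | t_frac > 1)) stop_ws("t_frac must lie in [0, 1]", "invalid_input")
  pressure$diastolic_mmHg +
    pressure$pulse_pressure_mmHg * waveform_shape(t_frac, systolic_fraction)
}

# Lumen radius a(t) at each frame (frame index 0-based internally; the
# returned vector has one entry per frame, frames 0 and n-1 at a0).
phantom_a_of_frame <- function(spec) {
  t_frac <- seq(0, 1, length.out = spec$n_frames)
  spec$inner_radius_mm +
    (spec$peak_inner_radius_mm - spec$inner_radius_mm) *
    waveform_shape(t_frac, spec$systolic_fraction)
}

# Angular compliance factor f(theta) in [compliance, 1]; identically 1 when
# there is no sector or compliance == 1. 10-degree cosine taper at each edge.
sector_factor <- function(theta, sector, taper_deg = 10) {
  if (is.null(sector) || sector$compliance >= 1) return(rep(1, length(theta)))
  mid <- (sector$start_deg + sector$end_deg) / 2 * pi / 180
  halfw <- abs(sector$end_deg - sector$start_deg) / 2 * pi / 180
  taper <- taper_deg * pi / 180
  d <- abs(atan2(sin(theta - mid), cos(theta - mid)))
  m <- numeric(length(theta))
  m[d <= halfw] <- 1
  ramp <- d > halfw & d < halfw + taper
  m[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - halfw) / taper))
  1 - (1 - sector$compliance) * m
}

# d/dtheta of sector_factor (analytic, for the ground-truth strain field).
sector_factor_deriv <- function(theta, sector, taper_deg = 10) {
  if (is.null(sector) || sector$compliance >= 1) return(rep(0, length(theta)))
  mid <- (sector$start_deg + sector$end_deg) / 2 * pi / 180
  halfw <- abs(sector$end_deg - sector$start_deg) / 2 * pi / 180
  taper <- taper_deg * pi / 180
  dd <- atan2(sin(theta - mid), cos(theta - mid))
  d <- abs(dd)
  out <- numeric(length(theta))
  ramp <- d > halfw & d < halfw + taper
  dm <- -0.5 * pi / taper * sin(pi * (d[ramp] - halfw) / taper) * sign(dd[ramp])
  out[ramp] <- -(1 - sector$compliance) * dm
  out
}

# Radial map of reference radius r at lumen radius a_t; smooth continuation
# inside the lumen (linear ramp) and beyond the wall (same sqrt map, which
# decays as c / 2r). Returns displaced radius.
radial_map <- function(r, a_t, a0) {
  cc <- a_t^2 - a0^2
  out <- r
  w <- r >= a0
  out[w] <- sqrt(r[w]^2 + cc)
  out[!w] <- r[!w] * (a_t / a0)
  out
}

#' Ground-truth displacement field of a phantom
#'
#' @param spec a [phantom_spec()].
#' @param points_mm n x 2 matrix of reference positions (mm, image coords).
#' @param frame 0-based frame index.
#' @return n x 2 matrix of displacements (mm).
#' @export
phantom_displacement <- function(spec, points_mm, frame) {
  a_t <- phantom_a_of_frame(spec)[frame + 1]
  ctr <- phantom_center_mm(spec)
  dx <- points_mm[, 1] - ctr[1]
  dy <- points_mm[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  f <- sector_factor(theta, spec$stiff_sector)
  rp <- r + f * (radial_map(r, a_t, spec$inner_radius_mm) - r)
  scale <- ifelse(r > 0, (rp - r) / r, 0)
  cbind(dx * scale, dy * scale)
}

phantom_center_mm <- function(spec) {
  c((spec$image_size_px[2] - 1) / 2, (spec$image_size_px[1] - 1) / 2) *
    spec$pixel_spacing_mm
}

#' Analytic area-weighted mean tensile principal Green strain
#'
#' The ground-truth twin of the measured strain curve: the mean, over the
#' reference wall annulus, of the larger principal Green-Lagrange strain of
#' the phantom's radial map at a given frame. For the homogeneous phantom the
#' closed form is `c * log(b0 / a0) / (b0^2 - a0^2)` with
#' `c = a(t)^2 - a0^2`; with a stiff sector the mean is evaluated by polar
#' midpoint quadrature of the exact deformation gradient.
#'
#' @param spec a [phantom_spec()].
#' @param frame 0-based frame index.
#' @param n_r,n_theta quadrature resolution (sector phantoms only).
#' @return mean principal Green strain (dimensionless fraction, >= 0).
#' @export
analytic_mean_principal_strain <- function(spec, frame, n_r = 600, n_theta = 720) {
  if (frame < 0 || frame >= spec$n_frames)
    stop_ws("frame index out of range", "invalid_input")
  a0 <- spec$inner_radius_mm; b0 <- spec$outer_radius_mm
  a_t <- phantom_a_of_frame(spec)[frame + 1]
  cc <- a_t^2 - a0^2
  if (cc == 0) return(0)
  if (is.null(spec$stiff_sector) || spec$stiff_sector$compliance >= 1) {
    return(cc * log(b0 / a0) / (b0^2 - a0^2))
  }
  r <- a0 + (seq_len(n_r) - 0.5) * (b0 - a0) / n_r
  th <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  f <- sector_factor(th, spec$stiff_sector)
  fp <- sector_factor_deriv(th, spec$stiff_sector)
  rp0 <- sqrt(r^2 + cc)          # homogeneous displaced radius
  u0 <- rp0 - r
  du0 <- r / rp0 - 1
  # grids: rows = radius, cols = theta
  R <- matrix(r, n_r, n_theta) + outer(u0, f)
  Frr <- 1 + outer(du0, f)
  Frt <- outer(u0 / r, fp)
  Ftt <- R / r
  Err <- 0.5 * (Frr^2 - 1)
  Ert <- 0.5 * (Frr * Frt)
  Ett <- 0.5 * (Frt^2 + Ftt^2 - 1)
  e1 <- (Err + Ett) / 2 + sqrt(((Err - Ett) / 2)^2 + Ert^2)
  wts <- matrix(r, n_r, n_theta)
  sum(e1 * wts) / sum(wts)
}

#' Systolic lumen radius that yields a target peak mean principal strain
#'
#' Inverts the homogeneous phantom's closed-form mean strain, so phantom
#' ladders can be specified by peak mean principal strain directly.
#'
#' @param target_strain desired peak area-weighted mean principal Green
#'   strain (fraction).
#' @param inner_radius_mm,outer_radius_mm end-diastolic annulus radii (mm).
#' @return `a_peak` in mm.
#' @export
a_peak_for_mean_strain <- function(target_strain, inner_radius_mm = 10,
                                   outer_radius_mm = 14) {
  a0 <- inner_radius_mm; b0 <- outer_radius_mm
  cc <- target_strain * (b0^2 - a0^2) / log(b0 / a0)
  sqrt(a0^2 + cc)
}

#' Generate a speckle phantom cine loop with ground truth
#'
#' Scatterers are placed uniformly at random over the field of view with
#' random amplitude and phase, advected by the ground-truth displacement
#' field at each frame (the texture is warped, never regenerated, so the
#' frame-to-frame speckle correlation is trackable), splatted onto the pixel
#' grid as a complex field, blurred by a Gaussian point-spread envelope,
#' envelope-detected and log-compressed to B-mode-like intensity. Additive
#' Gaussian noise (sd `noise_sigma`) is applied after log compression.
#' Everything is deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param pressure a [pressure_measurement()] attached to the loop metadata.
#' @param psf_sigma_mm Gaussian point-spread sd (mm).
#' @return list with `loop` (a `cine_loop`: `frames` list of H x W float
#'   matrices plus metadata) and `truth` (a `phantom_truth`: per-frame
#'   analytic mean principal strain, peak value and frame, displacement
#'   accessor).
#' @export
generate_phantom <- function(spec, pressure = pressure_measurement(120, 80),
                             psf_sigma_mm = 0.3) {
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  dx <- spec$pixel_spacing_mm
  ctr <- phantom_center_mm(spec)
  fov_x <- (W - 1) * dx; fov_y <- (H - 1) * dx
  margin <- 3 * psf_sigma_mm
  max_r <- sqrt(max(spec$peak_inner_radius_mm^2 - spec$inner_radius_mm^2 +
                      spec$outer_radius_mm^2, spec$outer_radius_mm^2))
  if (ctr[1] - max_r < margin || ctr[2] - max_r < margin ||
      ctr[1] + max_r > fov_x - margin || ctr[2] + max_r > fov_y - margin) {
    stop_ws("annulus (including systolic excursion) exceeds image bounds",
            "geometry_error")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n_sc <- round(spec$speckle_cell_density * fov_x * fov_y)
  sx <- runif(n_sc, 0, fov_x)
  sy <- runif(n_sc, 0, fov_y)
  amp <- sqrt(rnorm(n_sc)^2 + rnorm(n_sc)^2)   # Rayleigh amplitudes
  phs <- runif(n_sc, 0, 2 * pi)
  re <- amp * cos(phs); im <- amp * sin(phs)
  noise <- if (spec$noise_sigma > 0) {
    lapply(seq_len(spec$n_frames), function(k) {
      matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
    })
  } else NULL

  Ky <- gauss_toeplitz(H, psf_sigma_mm / dx)
  Kx <- gauss_toeplitz(W, psf_sigma_mm / dx)
  pts <- cbind(sx, sy)
  frames <- vector("list", spec$n_frames)
  norm_const <- NULL
  for (k in seq_len(spec$n_frames)) {
    u <- phantom_displacement(spec, pts, k - 1)
    px <- (pts[, 1] + u[, 1]) / dx
    py <- (pts[, 2] + u[, 2]) / dx
    fre <- splat_bilinear(px, py, re, H, W)
    fim <- splat_bilinear(px, py, im, H, W)
    env <- sqrt((Ky %*% fre %*% Kx)^2 + (Ky %*% fim %*% Kx)^2)
    img <- log1p(10 * env)
    if (is.null(norm_const)) norm_const <- stats::quantile(img, 0.99)
    img <- img / norm_const
    if (!is.null(noise)) img <- img + noise[[k]]
    # clamp to the B-mode intensity range and round to float32, the on-disk
    # sample format, so loops survive TIFF round trips bit-identically
    frames[[k]] <- round_float32(pmin(pmax(img, 0), 1))
  }

  mean_strain <- vapply(seq_len(spec$n_frames) - 1L, function(fr)
    analytic_mean_principal_strain(spec, fr), numeric(1))
  peak_frame <- which.max(mean_strain) - 1L
  loop <- structure(list(
    frames = frames, frame_rate_hz = spec$frame_rate_hz,
    pixel_spacing_mm = dx, pressure = pressure, seed = spec$seed
  ), class = "cine_loop")
  truth <- structure(list(
    mean_strain = mean_strain,
    peak_strain = max(mean_strain),
    peak_frame = peak_frame,
    displacement = function(points_mm, frame) phantom_displacement(spec, points_mm, frame),
    a_of_frame = phantom_a_of_frame(spec),
    spec = spec
  ), class = "phantom_truth")
  list(loop = loop, truth = truth)
}

# Dense Gaussian convolution operator (n x n Toeplitz), unit DC gain.
gauss_toeplitz <- function(n, sigma_px) {
  rad <- max(1L, ceiling(3 * sigma_px))
  g <- exp(-(seq(-rad, rad))^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  K <- matrix(0, n, n)
  for (o in seq(-rad, rad)) {
    i <- seq_len(n); j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- g[o + rad + 1]
  }
  K
}

# Bilinear splat of point amplitudes onto an H x W grid (0-based px coords).
splat_bilinear <- function(x, y, v, H, W) {
  keep <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
  x <- x[keep]; y <- y[keep]; v <- v[keep]
  x0 <- pmin(floor(x), W - 2); y0 <- pmin(floor(y), H - 2)
  fx <- x - x0; fy <- y - y0
  out <- numeric(H * W)
  add <- function(ix, iy, w) {
    idx <- ix * H + iy + 1
    s <- rowsum(v * w, idx)
    out[as.integer(rownames(s))] <<- out[as.integer(rownames(s))] + s[, 1]
  }
  add(x0, y0, (1 - fx) * (1 - fy))
  add(x0 + 1, y0, fx * (1 - fy))
  add(x0, y0 + 1, (1 - fx) * fy)
  add(x0 + 1, y0 + 1, fx * fy)
  matrix(out, H, W)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
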