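# Shared fixtures, memoized for the session so expensive phantoms are built
# once across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Annular ROI concentric with a phantom's wall.
phantom_roi <- function(spec, n = 128) {
  ctr <- wallstrain:::phantom_center_mm(spec)
  wall_roi(circle_contour(ctr, spec$inner_radius_mm, n),
           circle_contour(ctr, spec$outer_radius_mm, n))
}

# Small, fast phantom for unit tests (8 frames).
small_phantom <- function() cached("small_phantom", {
  spec <- phantom_spec(n_frames = 8L, seed = 3L)
  c(generate_phantom(spec), list(spec = spec))
})

# The reference 40-frame phantom used by the tracking-accuracy checks.
cycle_phantom <- function() cached("cycle_phantom", {
  spec <- phantom_spec(n_frames = 40L, seed = 11L)
  c(generate_phantom(spec), list(spec = spec))
})

default_mesh <- function(spec, n_circ = 48, n_rad = 3) {
  cached(sprintf("mesh_%d_%d_%.3f", n_circ, n_rad, spec$inner_radius_mm),
         build_quad_mesh(phantom_roi(spec), n_circ, n_rad))
}

# Full cycle tracking of the 40-frame phantom, shared between the drift and
# strain-recovery checks.
cycle_tracking <- function() cached("cycle_tracking", {
  ph <- cycle_phantom()
  mesh <- default_mesh(ph$spec)
  track_cycle(ph$loop, mesh)
})

rms <- function(m) sqrt(mean(m^2))

# Midpoint-rule quadrature oracle for the annulus mean tensile principal
# Green strain (independent of the package's closed form).
quadrature_mean_strain <- function(a0, b0, a_t, n = 20000) {
  cc <- a_t^2 - a0^2
  r <- a0 + (seq_len(n) - 0.5) * (b0 - a0) / n
  e1 <- 0.5 * ((r^2 + cc) / r^2 - 1)
  sum(e1 * r) / sum(r)
}
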