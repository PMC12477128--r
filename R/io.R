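# File formats and the end-to-end pipeline: cine loops as multi-page 32-bit
# float TIFF with a JSON metadata sidecar, ROI / mesh / displacement /
# result serialization, and run_pipeline() gluing mesh -> track -> strain.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

# Minimal multi-page grayscale TIFF writer, 32-bit IEEE float samples,
# uncompressed, little-endian, one strip per page. Written by hand because
# the available TIFF bindings only store scaled-integer samples; frames
# written here read back exactly (libtiff reads IEEE float natively).
write_float_tiff <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL); w2(42L)
  n <- length(frames)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  data_bytes <- 4 * H * W
  n_entries <- 10L
  ifd_bytes <- 2 + n_entries * 12 + 4
  # layout: header(8) | frame1 data | IFD1 | frame2 data | IFD2 | ...
  data_off <- function(k) 8 + (k - 1) * (data_bytes + ifd_bytes)
  ifd_off <- function(k) data_off(k) + data_bytes
  w4(ifd_off(1))
  entry <- function(tag, type, count, value) { w2(tag); w2(type); w4(count)
    if (type == 3) { w2(value); w2(0L) } else w4(value) }
  for (k in seq_len(n)) {
    writeBin(as.vector(t(frames[[k]])), con, size = 4, endian = "little")
    w2(n_entries)
    entry(256, 4, 1, W)               # ImageWidth
    entry(257, 4, 1, H)               # ImageLength
    entry(258, 3, 1, 32L)             # BitsPerSample
    entry(259, 3, 1, 1L)              # Compression: none
    entry(262, 3, 1, 1L)              # Photometric: BlackIsZero
    entry(273, 4, 1, data_off(k))     # StripOffsets
    entry(277, 3, 1, 1L)              # SamplesPerPixel
    entry(278, 4, 1, H)               # RowsPerStrip
    entry(279, 4, 1, data_bytes)      # StripByteCounts
    entry(339, 3, 1, 3L)              # SampleFormat: IEEE float
    w4(if (k < n) ifd_off(k + 1) else 0L)  # next IFD
  }
  invisible(path)
}

#' Write a cine loop to multi-page TIFF + JSON sidecar
#'
#' Frames are stored frame-major as 32-bit float grayscale; acquisition
#' metadata (frame rate, pixel spacing, cuff pressures, seed) goes to a JSON
#' sidecar next to the TIFF.
#'
#' @param loop a `cine_loop`.
#' @param path output TIFF path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_cine <- function(loop, path) {
  write_float_tiff(loop$frames, path)
  meta <- list(
    frame_rate_hz = loop$frame_rate_hz,
    pixel_spacing_mm = loop$pixel_spacing_mm,
    systolic_mmHg = loop$pressure$systolic_mmHg,
    diastolic_mmHg = loop$pressure$diastolic_mmHg,
    n_frames = length(loop$frames),
    seed = loop$seed
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cine loop from multi-page TIFF + JSON sidecar
#'
#' @param path TIFF path written by [write_cine()] (or any multi-page
#'   grayscale TIFF with a conforming sidecar).
#' @return a `cine_loop`. A frame rate below 50 fps triggers a warning
#'   (strain estimation needs dense temporal sampling) but still loads.
#' @export
read_cine <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(path)) stop_ws(paste("cine file not found:", path), "format_error")
  if (!file.exists(sp)) stop_ws(paste("missing metadata sidecar:", sp), "format_error")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("frame_rate_hz", "pixel_spacing_mm", "systolic_mmHg", "diastolic_mmHg"))
    if (is.null(meta[[f]]))
      stop_ws(paste("sidecar missing required field:", f), "format_error")
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  if (!is.null(meta$n_frames) && length(frames) != meta$n_frames)
    stop_ws(sprintf("frame-count mismatch: TIFF has %d pages, sidecar says %d",
                    length(frames), meta$n_frames), "format_error")
  if (meta$frame_rate_hz < 50)
    warning(sprintf("frame rate %.1f fps is below the recommended 50 fps",
                    meta$frame_rate_hz))
  structure(list(
    frames = frames, frame_rate_hz = meta$frame_rate_hz,
    pixel_spacing_mm = meta$pixel_spacing_mm,
    pressure = pressure_measurement(meta$systolic_mmHg, meta$diastolic_mmHg),
    seed = meta$seed %||% NA_integer_
  ), class = "cine_loop")
}

#' Write / read a wall ROI as JSON
#'
#' Format: `{"inner": [[x,y],...], "outer": [[x,y],...], "units": "mm",
#' "reference_frame": k}`.
#'
#' @param roi a [wall_roi()].
#' @param path JSON path.
#' @return `path` / the `wall_roi`.
#' @export
write_roi <- function(roi, path) {
  jsonlite::write_json(list(
    inner = unname(apply(roi$inner, 1, c, simplify = FALSE)),
    outer = unname(apply(roi$outer, 1, c, simplify = FALSE)),
    units = "mm", reference_frame = roi$reference_frame
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$inner) || is.null(j$outer))
    stop_ws("ROI JSON must contain 'inner' and 'outer' contours", "format_error")
  wall_roi(j$inner, j$outer, reference_frame = j$reference_frame %||% 0L)
}

#' Write / read a displacement sequence (CSV + JSON header)
#'
#' Displacements are stored as a long CSV (frame, node, ux_mm, uy_mm) next
#' to a JSON header with frame count, node count, reference frame and the
#' per-frame registration quality.
#'
#' @param disp a `displacement_sequence`.
#' @param path CSV path; the header replaces the extension with `.json`.
#' @export
write_displacement <- function(disp, path) {
  n <- length(disp$disp)
  tab <- do.call(rbind, lapply(seq_len(n), function(k) {
    d <- disp$disp[[k]]
    data.frame(frame = k - 1L, node = seq_len(nrow(d)) - 1L,
               ux_mm = d[, 1], uy_mm = d[, 2])
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(list(
    n_frames = n, n_nodes = nrow(disp$disp[[1]]),
    reference_frame = disp$reference_frame,
    frame_range = disp$frame_range,
    quality = disp$quality, converged = disp$converged
  ), sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_displacement
#' @export
read_displacement <- function(path) {
  hdr <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  tab <- utils::read.csv(path)
  disp <- lapply(seq_len(hdr$n_frames) - 1L, function(k) {
    d <- tab[tab$frame == k, ]
    d <- d[order(d$node), ]
    unname(cbind(d$ux_mm, d$uy_mm))
  })
  structure(list(disp = disp, quality = hdr$quality,
                 converged = hdr$converged,
                 reference_frame = hdr$reference_frame,
                 frame_range = hdr$frame_range),
            class = "displacement_sequence")
}

#' Pipeline configuration
#'
#' @param mesh_circ,mesh_rad mesh resolution (circumferential / radial
#'   element counts).
#' @param lambda_reg,pyramid_levels,max_iters tracking parameters, see
#'   [estimate_increment()].
#' @param measure strain measure, see [element_green_strain()].
#' @param colormap_range parametric image strain limits (fractions).
#' @param tercile_cutoffs c(c1, c2) in strain-fraction per mmHg.
#' @param seed RNG seed recorded with results.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mesh_circ = 48L, mesh_rad = 3L,
                            lambda_reg = 8, pyramid_levels = 3L,
                            max_iters = 50L, measure = "green",
                            colormap_range = c(0, 0.1),
                            tercile_cutoffs = c(0.0251, 0.038),
                            seed = 1L) {
  stopifnot(mesh_circ >= 4, mesh_rad >= 1, lambda_reg >= 0,
            pyramid_levels >= 1, max_iters >= 1,
            length(colormap_range) == 2, length(tercile_cutoffs) == 2)
  structure(list(mesh_circ = as.integer(mesh_circ), mesh_rad = as.integer(mesh_rad),
                 lambda_reg = lambda_reg, pyramid_levels = as.integer(pyramid_levels),
                 max_iters = as.integer(max_iters), measure = measure,
                 colormap_range = colormap_range,
                 tercile_cutoffs = tercile_cutoffs, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full single-scan pipeline
#'
#' Mesh the ROI, track the cycle, build the strain curve, normalize the peak
#' by pulse pressure, and measure the outer diameter. Deterministic given
#' identical inputs and configuration.
#'
#' @param config a [pipeline_config()].
#' @param loop a `cine_loop`.
#' @param roi a [wall_roi()].
#' @param pressure a [pressure_measurement()]; defaults to the loop's.
#' @param out_dir optional directory: writes `result.json`,
#'   `strain_curve.csv` and `parametric.png` there.
#' @return list with `eps_peak_fraction`, `eps_pp_percent_per_mmHg`,
#'   `peak_frame`, `diastolic_frame`, `diameter_cm`, `quality_summary`,
#'   plus the intermediate `mesh`, `displacement`, `curve`.
#' @export
run_pipeline <- function(config, loop, roi, pressure = NULL, out_dir = NULL) {
  pressure <- pressure %||% loop$pressure
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop_ws(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
              "pipeline_error"))
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  mesh <- stage("mesh", build_quad_mesh(roi, config$mesh_circ, config$mesh_rad))
  disp <- stage("track", track_cycle(loop, mesh,
                                     lambda_reg = config$lambda_reg,
                                     pyramid_levels = config$pyramid_levels,
                                     max_iters = config$max_iters))
  curve <- stage("strain", strain_curve(mesh, disp, loop$frame_rate_hz,
                                        measure = config$measure))
  ext <- select_cycle_extremes(curve)
  norm <- normalize_by_pp(curve$peak_value, pressure)
  diam <- measure_outer_diameter(roi)
  result <- list(
    eps_peak_fraction = curve$peak_value,
    eps_pp_percent_per_mmHg = norm$eps_pp,
    peak_frame = curve$peak_frame,
    diastolic_frame = ext[1],
    pulse_pressure_mmHg = norm$pulse_pressure_mmHg,
    diameter_cm = diam,
    quality_summary = list(mean_ncc = mean(disp$quality),
                           min_ncc = min(disp$quality),
                           all_converged = all(disp$converged)),
    config = unclass(config)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(result, file.path(out_dir, "result.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(
      data.frame(frame = seq_along(curve$values) - 1L,
                 time_s = curve$time_s %||% NA,
                 mean_principal_strain = curve$values),
      file.path(out_dir, "strain_curve.csv"), row.names = FALSE)
    overlay <- render_parametric_image(
      loop$frames[[curve$peak_frame + 1L]], mesh,
      curve$per_element[, curve$peak_frame + 1L],
      loop$pixel_spacing_mm, strain_range = config$colormap_range)
    png::writePNG(overlay, file.path(out_dir, "parametric.png"))
  }
  c(result, list(mesh = mesh, displacement = disp, curve = curve))
}
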