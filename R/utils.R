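# Internal numeric helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ws <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "wallstrain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Bilinear image interpolation at 0-based pixel coordinates
#'
#' Samples a grayscale image (matrix, rows = y, cols = x) at fractional pixel
#' positions. Coordinates are 0-based: (0, 0) is the center of the top-left
#' pixel. Positions outside the image are clamped to the border.
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of equal length, 0-based pixel coordinates.
#' @return numeric vector of sampled intensities.
#' @keywords internal
interp_bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(x0, nc - 2); y0 <- pmin(y0, nr - 2)
  fx <- x - x0; fy <- y - y0
  # 1-based linear indices of the four neighbours
  i00 <- (x0) * nr + y0 + 1
  i01 <- i00 + nr          # x0+1, y0
  i10 <- i00 + 1           # x0,   y0+1
  i11 <- i01 + 1
  v <- img[i00] * (1 - fx) * (1 - fy) +
    img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy +
    img[i11] * fx * fy
  v
}

# Central-difference gradient images (d/dx, d/dy) in intensity per pixel.
image_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]
  gx[, nc] <- img[, nc] - img[, nc - 1]
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]
  gy[nr, ] <- img[nr, ] - img[nr - 1, ]
  list(gx = gx, gy = gy)
}

# Separable box filter (odd width), replicate-padded borders.
box_filter <- function(img, width) {
  if (width <= 1) return(img)
  h <- (width - 1) %/% 2
  pad_run <- function(m) {
    cs <- apply(m, 2, cumsum)
    n <- nrow(m)
    idx_hi <- pmin(seq_len(n) + h, n)
    idx_lo <- seq_len(n) - h - 1
    top <- cs[idx_hi, , drop = FALSE]
    bot <- matrix(0, n, ncol(m))
    pos <- idx_lo >= 1
    bot[pos, ] <- cs[idx_lo[pos], , drop = FALSE]
    cnt <- idx_hi - pmax(idx_lo, 0)
    (top - bot) / cnt
  }
  t(pad_run(t(pad_run(img))))
}

# Local mean/variance normalization: (I - mu_w) / sqrt(var_w + eps).
normalize_local <- function(img, width = 9L, eps = 1e-4) {
  mu <- box_filter(img, width)
  v <- box_filter(img^2, width) - mu^2
  (img - mu) / sqrt(pmax(v, 0) + eps)
}

# Separable 5-tap binomial smoothing ([1 4 6 4 1]/16 per axis), replicated
# borders. Band-limits speckle before subpixel interpolation.
binom5 <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  sm <- function(x) {
    n <- nrow(x)
    y <- k[3] * x
    y <- y + k[2] * (x[c(1, 1:(n - 1)), , drop = FALSE] + x[c(2:n, n), , drop = FALSE])
    y + k[1] * (x[c(1, 1, 1:(n - 2)), , drop = FALSE] + x[c(3:n, n, n), , drop = FALSE])
  }
  t(sm(t(sm(m))))
}

# Downsample by 2 with a [1 2 1]/4 anti-alias kernel per axis.
pyr_down <- function(img) {
  k <- c(1, 2, 1) / 4
  sm <- function(m) {
    n <- nrow(m)
    up <- m[c(1, 1:(n - 1)), , drop = FALSE]
    dn <- m[c(2:n, n), , drop = FALSE]
    k[1] * up + k[2] * m + k[3] * dn
  }
  s <- t(sm(t(sm(img))))
  s[seq(1, nrow(s), by = 2), seq(1, ncol(s), by = 2), drop = FALSE]
}

# Round a numeric matrix to float32 precision (the TIFF sample format).
round_float32 <- function(m) {
  v <- readBin(writeBin(as.vector(m), raw(), size = 4L), "double",
               n = length(m), size = 4L)
  matrix(v, nrow(m), ncol(m))
}

# Round half away from zero at `digits` decimals (table formatting rule).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shoelace signed area of a closed polygon given as n x 2 matrix (no
# repeated end vertex). Positive for counterclockwise order in the stated
# coordinate convention (x right, y down does not change the algebra).
polygon_signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= min
}
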