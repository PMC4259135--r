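#' Cartesian IVUS image
#'
#' Wraps a 2-D intensity matrix together with the catheter-axis position.
#' Intensities are held as real numbers (0--255 after loading an 8-bit
#' image); pixel (i, j) is taken to sit at coordinates (i, j), 1-based.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param center Length-2 numeric `(row, col)` position of the catheter
#'   axis; must lie strictly inside the image bounds.
#' @return An object of class `cartesian_image` with elements `pixels`,
#'   `height`, `width`, `center`.
#' @export
cartesian_image <- function(pixels, center = (dim(pixels) + 1) / 2) {
  pixels <- as_intensity_matrix(pixels)
  center <- as.numeric(center)
  if (length(center) != 2L || anyNA(center)) {
    stop_invalid("center must be a length-2 numeric (row, col) vector")
  }
  if (center[1] <= 1 || center[1] >= nrow(pixels) ||
      center[2] <= 1 || center[2] >= ncol(pixels)) {
    stop_invalid("center must lie strictly inside the image bounds")
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         center = center),
    class = "cartesian_image"
  )
}

#' Polar IVUS image
#'
#' The pipeline's working representation: rows index radius (row 1 is the
#' smallest radius, at the catheter surface, increasing outward), columns
#' index angle with column j at theta = 2*pi*(j-1)/n_angles.  The angle
#' axis is periodic: column `n_angles + 1` wraps to column 1.
#'
#' @param pixels Numeric matrix, rows = radii, columns = angles.
#' @param radial_step Physical length per row in micrometres (metadata
#'   used when reporting distances in micrometres).
#' @return An object of class `polar_image` with elements `pixels`,
#'   `n_radii`, `n_angles`, `radial_step`.
#' @export
polar_image <- function(pixels, radial_step = 10) {
  pixels <- as_intensity_matrix(pixels)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop_invalid("a polar image needs at least 2 radii and 2 angles")
  }
  if (!is.numeric(radial_step) || length(radial_step) != 1L ||
      !is.finite(radial_step) || radial_step <= 0) {
    stop_invalid("radial_step must be a single positive number")
  }
  structure(
    list(pixels = pixels, n_radii = nrow(pixels), n_angles = ncol(pixels),
         radial_step = radial_step),
    class = "polar_image"
  )
}

as_intensity_matrix <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_invalid("pixels must be a numeric matrix")
  }
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop_invalid("all intensities must be finite and >= 0")
  }
  pixels
}

#' @export
print.cartesian_image <- function(x, ...) {
  cat(sprintf("<cartesian_image> %d x %d, center (%.2f, %.2f), range [%.1f, %.1f]\n",
              x$height, x$width, x$center[1], x$center[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("<polar_image> %d radii x %d angles, %.3g um/row, range [%.1f, %.1f]\n",
              x$n_radii, x$n_angles, x$radial_step,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Vectorised bilinear sampling of `mat` at real-valued (row, col) positions.
# Sample points outside [1, nrow] x [1, ncol] return `outside`; in-range
# points interpolate between the four surrounding pixel centres (corner
# indices clamped at the frame so edge samples degrade to linear/nearest).
bilinear_sample <- function(mat, y, x, outside = 0) {
  h <- nrow(mat); w <- ncol(mat)
  inside <- y >= 1 & y <= h & x >= 1 & x <= w
  out <- rep(outside, length(y))
  if (!any(inside)) return(out)
  yi <- y[inside]; xi <- x[inside]
  y0 <- pmin(floor(yi), h - 1L); x0 <- pmin(floor(xi), w - 1L)
  ty <- yi - y0; tx <- xi - x0
  v00 <- mat[cbind(y0, x0)]
  v01 <- mat[cbind(y0, x0 + 1)]
  v10 <- mat[cbind(y0 + 1, x0)]
  v11 <- mat[cbind(y0 + 1, x0 + 1)]
  out[inside] <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
  out
}

#' Resample a Cartesian IVUS image onto a polar grid
#'
#' Polar pixel (i, j) samples the Cartesian image by bilinear interpolation
#' at radius r = (i - 0.5) * r_max / n_radii from the catheter centre and
#' angle theta = 2*pi*(j-1)/n_angles.  The angle origin is the positive
#' x-axis (increasing column direction), with theta increasing towards
#' increasing row index.  Radii are taken at row centres (half-pixel
#' offset) so no row degenerates to r = 0.  Samples falling outside the
#' Cartesian frame yield 0, which keeps the region beyond the transducer
#' footprint dark.
#'
#' @param img A [cartesian_image()].
#' @param n_radii,n_angles Output grid size (positive integers).
#' @param r_max Largest sampled radius, in Cartesian pixels.
#' @param radial_step Micrometres per polar row recorded on the output.
#' @return A [polar_image()] of size `n_radii x n_angles`.
#' @export
to_polar <- function(img, n_radii, n_angles, r_max, radial_step = 10) {
  stopifnot(inherits(img, "cartesian_image"))
  check_count(n_radii, "n_radii"); check_count(n_angles, "n_angles")
  if (!is.numeric(r_max) || length(r_max) != 1L || !is.finite(r_max) ||
      r_max <= 0) {
    stop_invalid("r_max must be a single positive number")
  }
  r <- (seq_len(n_radii) - 0.5) * r_max / n_radii
  theta <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  yy <- img$center[1] + outer(r, sin(theta))
  xx <- img$center[2] + outer(r, cos(theta))
  vals <- bilinear_sample(img$pixels, as.vector(yy), as.vector(xx))
  polar_image(matrix(vals, n_radii, n_angles), radial_step = radial_step)
}

#' Render a polar image back onto a Cartesian grid
#'
#' Inverse resampling of [to_polar()]: each Cartesian output pixel maps to
#' (radius, angle) about `center` and interpolates the polar grid
#' bilinearly.  Angle interpolation wraps across the theta = 0 seam;
#' radius interpolation clamps at the first and last row; pixels with
#' radius greater than `r_max` are 0.
#'
#' @param img A [polar_image()].
#' @param out_height,out_width Output grid size (positive integers).
#' @param center Length-2 `(row, col)` catheter-axis position in the
#'   output frame.
#' @param r_max Radius, in output pixels, that the last polar row maps to.
#' @return A [cartesian_image()].
#' @export
to_cartesian <- function(img, out_height, out_width,
                         center = c((out_height + 1) / 2, (out_width + 1) / 2),
                         r_max = min(out_height, out_width) / 2 - 1) {
  stopifnot(inherits(img, "polar_image"))
  check_count(out_height, "out_height"); check_count(out_width, "out_width")
  if (r_max <= 0) stop_invalid("r_max must be positive")
  yy <- matrix(seq_len(out_height), out_height, out_width) - center[1]
  xx <- matrix(seq_len(out_width), out_height, out_width, byrow = TRUE) -
    center[2]
  r <- sqrt(yy^2 + xx^2)
  theta <- atan2(yy, xx) %% (2 * pi)
  fi <- pmin(pmax(r * img$n_radii / r_max + 0.5, 1), img$n_radii)
  fj <- theta * img$n_angles / (2 * pi) + 1
  j0 <- floor(fj); tj <- fj - j0
  jwrap <- function(j) ((j - 1) %% img$n_angles) + 1
  i0 <- pmin(floor(fi), img$n_radii - 1L); ti <- fi - i0
  p <- img$pixels
  idx <- function(i, j) p[cbind(as.vector(i), as.vector(jwrap(j)))]
  v00 <- idx(i0, j0);     v01 <- idx(i0, j0 + 1)
  v10 <- idx(i0 + 1, j0); v11 <- idx(i0 + 1, j0 + 1)
  ti <- as.vector(ti); tj <- as.vector(tj)
  vals <- (1 - ti) * ((1 - tj) * v00 + tj * v01) +
    ti * ((1 - tj) * v10 + tj * v11)
  vals[as.vector(r) > r_max] <- 0
  cartesian_image(matrix(vals, out_height, out_width), center = center)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop_invalid(sprintf("%s must be a positive integer", name))
  }
}

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("ivus_invalid_argument", "error")))
}
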