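#' Separability evaluation window
#'
#' The split window used by the image-separability statistic.  For an
#' evaluated pixel, region A is the `half_height` rows immediately above
#' it and region B the `half_height` rows starting at its own row, both
#' `width` columns wide and centred on the pixel's column.  In polar
#' coordinates A is therefore the inner-radius side and B the
#' outer-radius side of a candidate horizontal boundary.
#'
#' @param half_height Rows per sub-region, `h >= 1`.
#' @param width Window width in columns, odd, `w >= 1`.
#' @return An object of class `separability_window`.
#' @export
separability_window <- function(half_height = 5, width = 11) {
  check_count(half_height, "half_height")
  check_count(width, "width")
  if (width %% 2 == 0) stop_invalid("width must be odd")
  structure(list(half_height = as.integer(half_height),
                 width = as.integer(width)),
            class = "separability_window")
}

# Rows whose A/B regions fit entirely inside the radial extent.
window_row_range <- function(n_radii, window) {
  h <- window$half_height
  c(h + 1L, n_radii - h + 1L)
}

#' Image separability at one pixel
#'
#' Fisher-discriminant ratio of between-region to total variance over the
#' split window: with region means `IA`, `IB`, pooled mean `I` and the
#' `S = 2 h w` window pixels `I_k`,
#' `eta = (n_A (IA - I)^2 + n_B (IB - I)^2) / sum_k (I_k - I)^2`.
#' It equals 1 when the two regions are internally constant but
#' different, and 0 by convention when all window pixels are identical.
#' Windows crossing the radial edge return 0; the angle axis wraps.
#'
#' @param img A [polar_image()].
#' @param pixel Length-2 `(row, col)` position, 1-based.
#' @param window A [separability_window()].
#' @return Separability value in `[0, 1]`.
#' @export
separability_at <- function(img, pixel, window = separability_window()) {
  map <- separability_map(img, window, weighted = FALSE)
  map$values[pixel[1], pixel[2]]
}

#' Weighted image separability at one pixel
#'
#' Multiplies the separability by two intensity weights suited to IVUS:
#' `eta_w = eta * ((I_max - IA) / I_max) * (IB / I_max)^2`, where A is
#' the inner-radius region and B the outer-radius region.  Because the
#' tissue outside both the luminal and the adventitial boundary echoes
#' more strongly than the tissue inside, dark-inner/bright-outer
#' transitions are up-weighted and speckle edges with the wrong polarity
#' are suppressed.
#'
#' @inheritParams separability_at
#' @param i_max Intensity normaliser (> 0), normally the maximum
#'   intensity of the whole image.
#' @return Weighted separability value in `[0, 1]`.
#' @export
weighted_separability_at <- function(img, pixel,
                                     window = separability_window(),
                                     i_max = max(img$pixels)) {
  if (!is.numeric(i_max) || length(i_max) != 1L || i_max <= 0) {
    stop_invalid("i_max must be a single positive number")
  }
  map <- separability_map(img, window, weighted = TRUE, i_max = i_max)
  map$values[pixel[1], pixel[2]]
}

# Column-wrapped horizontal box sum over 2*half + 1 columns.
wrap_col_boxsum <- function(mat, half) {
  out <- mat
  for (dc in seq_len(half)) {
    out <- out + shift_polar(mat, 0L, dc) + shift_polar(mat, 0L, -dc)
  }
  out
}

#' Separability map of a polar image
#'
#' Evaluates the (optionally weighted) separability statistic at every
#' pixel via sliding-window sums.  `i_max` defaults to the maximum
#' intensity of the whole image; an all-zero image falls back to
#' `i_max = 1` and yields an all-zero map.  Rows whose window would cross
#' the radial edge are 0.
#'
#' @inheritParams separability_at
#' @param weighted If `TRUE`, apply the IVUS intensity weights.
#' @param i_max Intensity normaliser for the weighted statistic.
#' @return An object of class `separability_map` with elements `values`
#'   (matrix in `[0, 1]`, same shape as the image), `window`,
#'   `i_max_used`, `weighted`.
#' @export
separability_map <- function(img, window = separability_window(),
                             weighted = TRUE, i_max = NULL) {
  stopifnot(inherits(img, "polar_image"),
            inherits(window, "separability_window"))
  h <- window$half_height; w <- window$width
  n <- img$n_radii; m <- img$n_angles
  if (2L * h > n) stop_invalid("window taller than the image")
  if (w > m) stop_invalid("window wider than the image")
  if (is.null(i_max)) {
    i_max <- max(img$pixels)
    if (i_max <= 0) i_max <- 1  # degenerate all-zero image
  }
  if (i_max <= 0) stop_invalid("i_max must be positive")

  p <- img$pixels
  half_w <- (w - 1L) %/% 2L
  s1 <- wrap_col_boxsum(p, half_w)      # row-wise horizontal sums
  s2 <- wrap_col_boxsum(p^2, half_w)
  c1 <- apply(rbind(0, s1), 2, cumsum)  # c1[i+1, ] = colwise cumsum through row i
  c2 <- apply(rbind(0, s2), 2, cumsum)

  n_sub <- h * w                        # pixels per sub-region
  S <- 2 * n_sub
  vals <- matrix(0, n, m)
  rows <- seq.int(h + 1L, n - h + 1L)
  if (length(rows)) {
    a1 <- c1[rows, , drop = FALSE] - c1[rows - h, , drop = FALSE]
    b1 <- c1[rows + h, , drop = FALSE] - c1[rows, , drop = FALSE]
    t2 <- c2[rows + h, , drop = FALSE] - c2[rows - h, , drop = FALSE]
    tot1 <- a1 + b1
    mu <- tot1 / S
    mu_a <- a1 / n_sub
    mu_b <- b1 / n_sub
    num <- n_sub * ((mu_a - mu)^2 + (mu_b - mu)^2)
    den <- t2 - S * mu^2
    eta <- ifelse(den > 0, num / den, 0)
    eta <- pmin(pmax(eta, 0), 1)
    if (weighted) {
      eta <- eta * pmax((i_max - mu_a) / i_max, 0) * (mu_b / i_max)^2
      eta <- pmin(pmax(eta, 0), 1)
    }
    vals[rows, ] <- eta
  }
  structure(list(values = vals, window = window, i_max_used = i_max,
                 weighted = weighted),
            class = "separability_map")
}

#' @export
print.separability_map <- function(x, ...) {
  cat(sprintf("<separability_map>%s %d x %d, window h=%d w=%d, max %.3f\n",
              if (x$weighted) " weighted" else "",
              nrow(x$values), ncol(x$values),
              x$window$half_height, x$window$width, max(x$values)))
  invisible(x)
}
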