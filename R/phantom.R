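#' Synthetic polar IVUS phantom specification
#'
#' Describes a three-layer polar IVUS phantom: a dark lumen, a
#' mid-intensity plaque band and a bright adventitia, separated by two
#' smooth periodic boundary curves (luminal inside adventitial),
#' degraded by a Gaussian point-spread blur and multiplicative speckle.
#' Each boundary curve is a base radius plus two low-order sinusoidal
#' harmonics with phases drawn from the seeded generator, so curves stay
#' smooth and angularly periodic.
#'
#' @param n_radii,n_angles Grid size (default 128 x 256).
#' @param lb_base,ab_base Base radii (rows) of the luminal and
#'   adventitial boundaries.
#' @param lb_amp,ab_amp Length-2 amplitudes (rows) of the first and
#'   second harmonic of each curve; kept below 10% of the base radius.
#' @param layer_means Named intensities (0--255) for `lumen`, `plaque`,
#'   `adventitia`; must be strictly increasing in that order, mirroring
#'   the brighter-outside echo structure of IVUS.
#' @param speckle_sigma Scale of the multiplicative noise (see
#'   [generate_phantom()]).
#' @param blur_sigma Gaussian point-spread sigma, in pixels.
#' @param noise_model `"gaussian"` (clipped multiplicative Gaussian,
#'   default, with closed-form moments) or `"rayleigh"` (unit-mean
#'   Rayleigh envelope, closer to coherent-imaging speckle).
#' @param radial_step Micrometres per row recorded on the image.
#' @param seed Integer RNG seed; identical seeds give identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_radii = 128, n_angles = 256,
                         lb_base = 45, ab_base = 85,
                         lb_amp = c(4, 2), ab_amp = c(5, 2.5),
                         layer_means = c(lumen = 25, plaque = 90,
                                         adventitia = 190),
                         speckle_sigma = 0.3, blur_sigma = 1,
                         noise_model = c("gaussian", "rayleigh"),
                         radial_step = 10, seed = 1L) {
  check_count(n_radii, "n_radii"); check_count(n_angles, "n_angles")
  noise_model <- match.arg(noise_model)
  lm <- layer_means
  if (is.null(names(lm)) ||
      !all(c("lumen", "plaque", "adventitia") %in% names(lm))) {
    stop_invalid("layer_means must name lumen, plaque and adventitia")
  }
  lm <- lm[c("lumen", "plaque", "adventitia")]
  if (!(lm[1] < lm[2] && lm[2] < lm[3])) {
    stop_invalid("layer means must increase: lumen < plaque < adventitia")
  }
  if (any(lm < 0) || any(lm > 255)) stop_invalid("layer means must be in [0, 255]")
  amp_lb <- sum(abs(lb_amp)); amp_ab <- sum(abs(ab_amp))
  if (lb_base - amp_lb <= 1 || ab_base + amp_ab >= n_radii) {
    stop_invalid("boundary curves must stay inside (1, n_radii)")
  }
  if (lb_base + amp_lb >= ab_base - amp_ab) {
    stop_invalid("the luminal curve must stay strictly inside the adventitial curve")
  }
  if (speckle_sigma < 0 || blur_sigma < 0) {
    stop_invalid("noise and blur scales must be >= 0")
  }
  structure(list(n_radii = as.integer(n_radii),
                 n_angles = as.integer(n_angles),
                 lb_base = lb_base, ab_base = ab_base,
                 lb_amp = lb_amp, ab_amp = ab_amp,
                 layer_means = lm, speckle_sigma = speckle_sigma,
                 blur_sigma = blur_sigma, noise_model = noise_model,
                 radial_step = radial_step, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate code with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Separable Gaussian blur on the polar grid: angle axis wraps, radius
# axis replicates its border rows.
gaussian_blur_polar <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- 0
  for (t in seq_along(k)) out <- out + k[t] * shift_polar(mat, t - rad - 1L, 0L)
  mat <- out
  out <- 0
  for (t in seq_along(k)) out <- out + k[t] * shift_polar(mat, 0L, t - rad - 1L)
  out
}

#' Generate a synthetic polar IVUS phantom
#'
#' Builds the piecewise-constant three-layer image from the spec's
#' boundary curves (a pixel in row i, column j belongs to the lumen when
#' `i <= lb(j)`, to the plaque when `lb(j) < i <= ab(j)`, else to the
#' adventitia), applies the Gaussian blur, then multiplies each pixel by
#' a speckle factor: `1 + e` with `e ~ N(0, speckle_sigma)` for the
#' Gaussian model, or a unit-mean Rayleigh envelope with scale tied to
#' `speckle_sigma` for the Rayleigh model.  The result is clipped to
#' `[0, 255]`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `ivus_phantom`: `image` (a [polar_image()]),
#'   `lb` and `ab` (the exact generating [boundary_curve()]s), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    m <- spec$n_angles; n <- spec$n_radii
    theta <- 2 * pi * (seq_len(m) - 1) / m
    ph <- stats::runif(4, 0, 2 * pi)
    lb <- spec$lb_base + spec$lb_amp[1] * sin(theta + ph[1]) +
      spec$lb_amp[2] * sin(2 * theta + ph[2])
    ab <- spec$ab_base + spec$ab_amp[1] * sin(theta + ph[3]) +
      spec$ab_amp[2] * sin(2 * theta + ph[4])

    rows <- matrix(seq_len(n), n, m)
    lbm <- matrix(lb, n, m, byrow = TRUE)
    abm <- matrix(ab, n, m, byrow = TRUE)
    lm <- spec$layer_means
    img <- lm[["lumen"]] +
      (lm[["plaque"]] - lm[["lumen"]]) * (rows > lbm) +
      (lm[["adventitia"]] - lm[["plaque"]]) * (rows > abm)
    img <- gaussian_blur_polar(img, spec$blur_sigma)
    if (spec$speckle_sigma > 0) {
      fac <- if (spec$noise_model == "gaussian") {
        1 + stats::rnorm(n * m, 0, spec$speckle_sigma)
      } else {
        # unit-mean Rayleigh envelope whose sd is speckle_sigma
        s <- spec$speckle_sigma / sqrt(2 - pi / 2)
        r <- s * sqrt(-2 * log(stats::runif(n * m)))
        r - s * sqrt(pi / 2) + 1
      }
      img <- img * matrix(fac, n, m)
    }
    img <- pmin(pmax(img, 0), 255)
    structure(list(image = polar_image(img, radial_step = spec$radial_step),
                   lb = boundary_curve(lb, "LB"),
                   ab = boundary_curve(ab, "AB"),
                   spec = spec),
              class = "ivus_phantom")
  })
}

#' Root-mean-square error between two boundary curves
#'
#' `rmse_px = sqrt(mean((detected - truth)^2))` over the angular
#' columns; `rmse_um = rmse_px * radial_step` converts to micrometres.
#'
#' @param detected,truth Numeric vectors (e.g. [boundary_curve()]s) of
#'   equal length.
#' @param radial_step Micrometres per row.
#' @return A list with `rmse_px` and `rmse_um`.
#' @export
evaluate_rmse <- function(detected, truth, radial_step = 10) {
  if (length(detected) != length(truth)) {
    stop_invalid("curves must have the same number of angles")
  }
  rmse <- sqrt(mean((as.numeric(detected) - as.numeric(truth))^2))
  list(rmse_px = rmse, rmse_um = rmse * radial_step)
}
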