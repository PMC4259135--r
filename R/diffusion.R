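#' Diffusion filter parameters
#'
#' Bundles the edge-stopping constant, the diffusion strengths and the
#' iteration count for both variants of the Perona-Malik diffusion (PMD)
#' filter.  The normal filter diffuses towards the four axial neighbours
#' with a single strength `lambda`; the modified filter diffuses towards
#' all eight neighbours with a per-direction strength, by default weaker
#' across the near-horizontal plaque boundaries (north/south) than along
#' them: `lambda_N = lambda_S = 1`, all other directions `1.2`.
#'
#' Stability requires `max(lambda) <= |phi_s|` (4 for the normal
#' neighbourhood, 8 for the modified one): since the edge-stopping
#' coefficient never exceeds 1, each update is then a convex combination
#' of the pixel and its neighbours, which gives the maximum principle.
#'
#' @param K Edge-stopping constant in intensity units (> 0).  Gradients
#'   well below `K` diffuse freely; gradients above `K` fall in the
#'   sharpening branch of the rational flux function and are preserved.
#'   The default 12 follows the usual rule of placing `K` below the
#'   per-row gradient of the weakest boundary to keep (about 16 grey
#'   levels for a 65-level lumen-plaque step spread by the point-spread
#'   function over ~4 rows) and above the speckle gradient scale of the
#'   dark lumen (about 11 at 30% multiplicative noise).
#' @param lambda Scalar strength for the normal 4-neighbour filter
#'   (`0 <= lambda <= 4`).
#' @param lambda_dirs Named numeric vector of per-direction strengths for
#'   the modified 8-neighbour filter; names must be
#'   `N, S, E, W, NE, NW, SE, SW` (any order), each in `[0, 8]`.
#' @param n_iter Number of diffusion iterations (>= 0).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(K = 12,
                             lambda = 1,
                             lambda_dirs = c(N = 1, S = 1, E = 1.2, W = 1.2,
                                             NE = 1.2, NW = 1.2,
                                             SE = 1.2, SW = 1.2),
                             n_iter = 20) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    stop_invalid("K must be a single positive number")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_invalid("lambda must be a single number >= 0")
  }
  dirs <- c("N", "S", "E", "W", "NE", "NW", "SE", "SW")
  if (is.null(names(lambda_dirs)) || !all(dirs %in% names(lambda_dirs))) {
    stop(errorCondition(
      paste("lambda_dirs must name all eight directions:",
            paste(setdiff(dirs, names(lambda_dirs)), collapse = ", "),
            "missing"),
      class = c("ivus_config_error", "error")))
  }
  lambda_dirs <- lambda_dirs[dirs]
  if (any(!is.finite(lambda_dirs)) || any(lambda_dirs < 0)) {
    stop_invalid("all per-direction strengths must be finite and >= 0")
  }
  if (lambda > 4) {
    stop(errorCondition("normal-filter stability requires lambda <= 4",
                        class = c("ivus_config_error", "error")))
  }
  if (max(lambda_dirs) > 8) {
    stop(errorCondition("modified-filter stability requires max(lambda_k) <= 8",
                        class = c("ivus_config_error", "error")))
  }
  if (!is.numeric(n_iter) || length(n_iter) != 1L || n_iter < 0 ||
      n_iter != round(n_iter)) {
    stop_invalid("n_iter must be a non-negative integer")
  }
  structure(list(K = K, lambda = lambda, lambda_dirs = lambda_dirs,
                 n_iter = as.integer(n_iter)),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("<diffusion_params> K = %g, lambda = %g, n_iter = %d\n",
              x$K, x$lambda, x$n_iter))
  cat("  lambda_dirs:",
      paste(sprintf("%s=%g", names(x$lambda_dirs), x$lambda_dirs),
            collapse = ", "), "\n")
  invisible(x)
}

#' Edge-stopping function
#'
#' The rational edge-stopping coefficient
#' `g(|grad I|) = 1 / (1 + (|grad I| / K)^2)`: equal to 1 at zero
#' gradient and strictly decreasing, so diffusion is gated off across
#' strong edges.
#'
#' @param gradient_magnitude Non-negative gradient magnitude(s).
#' @param K Edge-stopping constant (> 0), in the same intensity units.
#' @return Coefficients in `(0, 1]`, same shape as `gradient_magnitude`.
#' @examples
#' edge_stopping(0, 30)          # 1
#' edge_stopping(30, 30)         # 0.5
#' edge_stopping(90, 30)         # 0.1
#' @export
edge_stopping <- function(gradient_magnitude, K) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    stop_invalid("K must be a single positive number")
  }
  1 / (1 + (gradient_magnitude / K)^2)
}

# Neighbour view of a polar-grid matrix, offset (dr, dc) in (row, col).
# Columns (angle) wrap periodically; rows (radius) reflect: the virtual
# neighbour beyond the first/last row is the border pixel itself, so the
# corresponding difference is zero (Neumann, zero-flux).
shift_polar <- function(mat, dr, dc) {
  n <- nrow(mat); m <- ncol(mat)
  ri <- seq_len(n) + dr
  ri[ri < 1L] <- 1L
  ri[ri > n] <- n
  ci <- ((seq_len(m) - 1L + dc) %% m) + 1L
  mat[ri, ci, drop = FALSE]
}

.dir_offsets <- list(
  N = c(-1L, 0L), S = c(1L, 0L), E = c(0L, 1L), W = c(0L, -1L),
  NE = c(-1L, 1L), NW = c(-1L, -1L), SE = c(1L, 1L), SW = c(1L, -1L)
)

#' Directional intensity differences on the polar grid
#'
#' For each requested compass direction k, returns the difference
#' `I_p - I_s` between the neighbour in that direction and the pixel
#' itself.  North is towards smaller radius (row 1), east towards
#' increasing angle.  The angle axis wraps; the radius axis reflects
#' (differences across the first/last row are zero).
#'
#' @param pixels Numeric matrix (rows = radius, cols = angle).
#' @param directions Character vector of direction labels.
#' @return Named list of difference matrices.
#' @export
directional_differences <- function(pixels,
                                    directions = names(.dir_offsets)) {
  bad <- setdiff(directions, names(.dir_offsets))
  if (length(bad)) {
    stop_invalid(paste("unknown direction(s):", paste(bad, collapse = ", ")))
  }
  lapply(stats::setNames(directions, directions), function(k) {
    off <- .dir_offsets[[k]]
    shift_polar(pixels, off[1], off[2]) - pixels
  })
}

#' One step of the normal 4-neighbour Perona-Malik filter
#'
#' Discrete Perona-Malik update
#' `I_s <- I_s + (lambda / 4) * sum_p g(|I_p - I_s|) * (I_p - I_s)`
#' over the four axial neighbours (N, S, E, W).
#'
#' @param img A [polar_image()].
#' @param params A [diffusion_params()]; uses `K` and `lambda`.
#' @return The diffused [polar_image()].
#' @export
pmd_step_normal <- function(img, params) {
  stopifnot(inherits(img, "polar_image"), inherits(params, "diffusion_params"))
  d <- directional_differences(img$pixels, c("N", "S", "E", "W"))
  flux <- 0
  for (dk in d) flux <- flux + edge_stopping(abs(dk), params$K) * dk
  polar_image(img$pixels + (params$lambda / 4) * flux,
              radial_step = img$radial_step)
}

#' One step of the modified 8-direction Perona-Malik filter
#'
#' Update
#' `I_s <- I_s + (1 / 8) * sum_k lambda_k * g(|D_k|) * D_k`
#' with `D_k = I_k - I_s` over the eight compass directions.  Direction
#' strengths `lambda_k` let diffusion across the near-horizontal plaque
#' boundaries (N, S in polar coordinates) be weaker than along them, so
#' speckle is smoothed while the boundaries stay sharp.  Diagonal
#' differences enter at their raw scale (no 1/sqrt(2) distance
#' normalisation); the default strengths are defined on that scale.
#'
#' @inheritParams pmd_step_normal
#' @return The diffused [polar_image()].
#' @export
pmd_step_modified <- function(img, params) {
  stopifnot(inherits(img, "polar_image"), inherits(params, "diffusion_params"))
  d <- directional_differences(img$pixels)
  flux <- 0
  for (k in names(d)) {
    dk <- d[[k]]
    flux <- flux + params$lambda_dirs[[k]] * edge_stopping(abs(dk), params$K) * dk
  }
  polar_image(img$pixels + flux / 8, radial_step = img$radial_step)
}

#' Run the diffusion filter for several iterations
#'
#' Applies [pmd_step_normal()] or [pmd_step_modified()] `n_iter` times,
#' starting from the input image (`n_iter = 0` returns it unchanged).
#'
#' @inheritParams pmd_step_normal
#' @param mode `"normal"` or `"modified"`.
#' @return The diffused [polar_image()].
#' @export
run_diffusion <- function(img, params = diffusion_params(),
                          mode = c("modified", "normal")) {
  if (!is.character(mode) || !all(mode %in% c("modified", "normal"))) {
    stop_invalid("mode must be 'normal' or 'modified'")
  }
  mode <- match.arg(mode)
  step <- if (mode == "modified") pmd_step_modified else pmd_step_normal
  for (i in seq_len(params$n_iter)) img <- step(img, params)
  img
}
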