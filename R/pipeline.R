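#' Default pipeline configuration
#'
#' Nested list of every tunable pipeline setting with its default.
#' `run_pipeline()` merges a user configuration over these defaults and
#' rejects unknown keys.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    input = list(path = NULL,          # polar grayscale PNG/TIFF; NULL -> phantom
                 cartesian = FALSE,    # set TRUE to polar-transform first
                 center = NULL, n_radii = 128L, n_angles = 256L,
                 r_max = NULL, radial_step = 10),
    phantom = list(enabled = FALSE, n_radii = 128L, n_angles = 256L,
                   lb_base = 45, ab_base = 85,
                   lb_amp = c(4, 2), ab_amp = c(5, 2.5),
                   layer_means = c(lumen = 25, plaque = 90, adventitia = 190),
                   speckle_sigma = 0.3, blur_sigma = 1,
                   noise_model = "gaussian", radial_step = 10, seed = 1L),
    diffusion = list(mode = "modified", K = 12,
                     lambda = 1,
                     lambda_dirs = c(N = 1, S = 1, E = 1.2, W = 1.2,
                                     NE = 1.2, NW = 1.2, SE = 1.2, SW = 1.2),
                     n_iter = 20L),
    separability = list(half_height = 5L, width = 11L),
    boundary = list(R = 8L, n_anchors = 8L, min_gap = 10, margin = 8,
                    top_m = 3L, overlap = 0.6),
    output = list(dir = ".", prefix = "ivus", overlay = TRUE,
                  filtered = TRUE, map = TRUE)
  )
}

#' Merge a user configuration over the defaults
#'
#' Recursively overlays `user` on `defaults`, rejecting unknown keys
#' with the offending key path named.
#'
#' @param user Nested list of overrides (e.g. parsed YAML).
#' @param defaults Defaults to merge into.
#' @param path Internal; key path prefix for error messages.
#' @return The fully-resolved configuration list.
#' @export
merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop(errorCondition(sprintf("config section '%s' must be a mapping", path),
                        class = c("ivus_config_error", "error")))
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(errorCondition(
      sprintf("unknown config key(s): %s",
              paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                     collapse = ", ")),
      class = c("ivus_config_error", "error")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, ".", k))
    } else {
      v <- user[[k]]
      if (!is.null(names(defaults[[k]])) && is.list(v)) v <- unlist(v)
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Boundary curves as a tidy data frame
#'
#' @param lb,ab [boundary_curve()]s on the same angular grid.
#' @param radial_step Micrometres per row.
#' @return Data frame with `boundary_label`, `angle_index`, `angle_rad`,
#'   `radius_px`, `radius_um`; one row per column per boundary.
#' @export
curves_to_df <- function(lb, ab, radial_step = 10) {
  m <- length(lb)
  one <- function(curve, label) {
    data.frame(boundary_label = label,
               angle_index = seq_len(m) - 1L,
               angle_rad = 2 * pi * (seq_len(m) - 1) / m,
               radius_px = as.numeric(curve),
               radius_um = as.numeric(curve) * radial_step)
  }
  rbind(one(lb, "LB"), one(ab, "AB"))
}

#' Render detected curves over a polar image
#'
#' @param img A [polar_image()].
#' @param lb,ab [boundary_curve()]s.
#' @return An `n_radii x n_angles x 3` RGB array in `[0, 1]` with the
#'   luminal curve in red and the adventitial curve in green.
#' @export
render_overlay <- function(img, lb, ab) {
  g <- pmin(pmax(img$pixels, 0), 255) / 255
  arr <- array(g, c(img$n_radii, img$n_angles, 3))
  draw <- function(arr, curve, rgb) {
    rows <- pmin(pmax(round(as.numeric(curve)), 1), img$n_radii)
    idx <- cbind(rows, seq_along(rows))
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[idx] <- rgb[ch]
      arr[, , ch] <- plane
    }
    arr
  }
  arr <- draw(arr, lb, c(1, 0, 0))
  draw(arr, ab, c(0, 1, 0))
}

#' Run the full boundary-detection pipeline from a configuration
#'
#' Loads (or synthesises) a polar IVUS image, runs diffusion filtering,
#' weighted separability, seed placement and Takagi-Sugeno boundary
#' inference, and writes the filtered image, the separability map, the
#' curves CSV, an overlay PNG and the fully-resolved configuration YAML
#' next to each other.  When the input is a phantom (or a truth CSV is
#' available) the boundary RMSE against the ground truth is computed and
#' reported.
#'
#' @param config Nested list overriding [default_config()]; unknown keys
#'   are rejected with the offending key named.
#' @param dry_run If `TRUE`, resolve and return the configuration
#'   without reading or writing anything.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the resolved `config`, the
#'   `detection`, the output `paths`, and `rmse` (or `NULL`).
#' @export
run_pipeline <- function(config = list(), dry_run = FALSE, quiet = FALSE) {
  cfg <- merge_config(config)
  if (dry_run) {
    cat(yaml::as.yaml(resolved_config_list(cfg)))
    return(invisible(list(config = cfg, detection = NULL, paths = NULL,
                          rmse = NULL)))
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  truth <- NULL
  if (isTRUE(cfg$phantom$enabled) || is.null(cfg$input$path)) {
    ph_args <- cfg$phantom[setdiff(names(cfg$phantom), "enabled")]
    spec <- do.call(phantom_spec, ph_args)
    ph <- generate_phantom(spec)
    img <- ph$image
    truth <- ph
    say("generated phantom %d x %d (seed %d)", img$n_radii, img$n_angles,
        spec$seed)
  } else {
    px <- read_gray_image(cfg$input$path)
    if (isTRUE(cfg$input$cartesian)) {
      ctr <- cfg$input$center
      if (is.null(ctr)) ctr <- (dim(px) + 1) / 2
      r_max <- cfg$input$r_max
      if (is.null(r_max)) r_max <- min(dim(px)) / 2 - 1
      img <- to_polar(cartesian_image(px, center = ctr),
                      n_radii = cfg$input$n_radii,
                      n_angles = cfg$input$n_angles, r_max = r_max,
                      radial_step = cfg$input$radial_step)
    } else {
      img <- polar_image(px, radial_step = cfg$input$radial_step)
    }
    say("loaded %s (%d x %d polar)", cfg$input$path, img$n_radii,
        img$n_angles)
  }

  dp <- diffusion_params(K = cfg$diffusion$K, lambda = cfg$diffusion$lambda,
                         lambda_dirs = cfg$diffusion$lambda_dirs,
                         n_iter = cfg$diffusion$n_iter)
  win <- separability_window(cfg$separability$half_height,
                             cfg$separability$width)
  bd <- cfg$boundary
  det <- detect_boundaries(img, dparams = dp, window = win, R = bd$R,
                           mode = cfg$diffusion$mode,
                           n_anchors = bd$n_anchors, min_gap = bd$min_gap,
                           margin = bd$margin, top_m = bd$top_m,
                           overlap = bd$overlap)

  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(cfg$output$dir, cfg$output$prefix)
  paths <- list(curves = paste0(pre, "_curves.csv"),
                config = paste0(pre, "_config.yaml"))
  utils::write.csv(curves_to_df(det$lb, det$ab, img$radial_step),
                   paths$curves, row.names = FALSE)
  if (isTRUE(cfg$output$filtered)) {
    paths$filtered <- paste0(pre, "_filtered.png")
    write_gray_image(det$filtered$pixels, paths$filtered)
  }
  if (isTRUE(cfg$output$map)) {
    paths$map <- paste0(pre, "_sepmap.tiff")
    write_float_tiff(det$map, paths$map)
  }
  if (isTRUE(cfg$output$overlay)) {
    paths$overlay <- paste0(pre, "_overlay.png")
    png::writePNG(render_overlay(img, det$lb, det$ab), paths$overlay)
  }
  yaml::write_yaml(resolved_config_list(cfg), paths$config)

  rmse <- NULL
  if (!is.null(truth)) {
    rmse <- list(lb = evaluate_rmse(det$lb, truth$lb, img$radial_step),
                 ab = evaluate_rmse(det$ab, truth$ab, img$radial_step))
    say("RMSE vs truth: LB %.2f rows (%.1f um), AB %.2f rows (%.1f um)",
        rmse$lb$rmse_px, rmse$lb$rmse_um, rmse$ab$rmse_px, rmse$ab$rmse_um)
  }
  say("wrote %s", paste(unlist(paths), collapse = ", "))
  invisible(list(config = cfg, detection = det, paths = paths, rmse = rmse))
}

# YAML-friendly copy of the resolved config (named vectors -> lists).
resolved_config_list <- function(cfg) {
  rapply(cfg, function(x) {
    if (!is.null(names(x)) && !is.list(x)) as.list(x) else x
  }, how = "replace")
}
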