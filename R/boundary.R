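#' Boundary curve
#'
#' A detected or ground-truth vessel boundary in polar coordinates: one
#' real-valued radius (in rows) per angular column.  The curve is
#' angularly periodic.
#'
#' @param radii Numeric vector, one radius per column.
#' @param label `"LB"` (luminal) or `"AB"` (adventitial).
#' @return A numeric vector of class `boundary_curve` with a `label`
#'   attribute.
#' @export
boundary_curve <- function(radii, label = c("LB", "AB")) {
  label <- match.arg(label)
  radii <- as.numeric(radii)
  if (length(radii) < 2L || anyNA(radii)) {
    stop_invalid("a boundary curve needs >= 2 finite radii")
  }
  structure(radii, label = label, class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve %s> %d angles, radius %.1f-%.1f rows\n",
              attr(x, "label"), length(x), min(x), max(x)))
  invisible(x)
}

# Signed angular offset wrapped to [-pi, pi).
wrap_angle <- function(delta) {
  ((delta + pi) %% (2 * pi)) - pi
}

# Periodic linear interpolation of values known at anchor columns onto
# all m columns (columns are 1-based, angle wraps at column m + 1 -> 1).
interp_periodic <- function(anchor_cols, anchor_vals, m) {
  k <- length(anchor_cols)
  ord <- order(anchor_cols)
  ac <- anchor_cols[ord]; av <- anchor_vals[ord]
  acx <- c(ac, ac[1] + m)            # closing segment across the seam
  avx <- c(av, av[1])
  cols <- seq_len(m)
  colsx <- ifelse(cols < ac[1], cols + m, cols)
  stats::approx(acx, avx, xout = colsx, rule = 2)$y
}

#' Place seed points and build per-angle search bands
#'
#' At each of `n_anchors` evenly-spaced anchor angles, the radial profile
#' of the separability map (averaged over `profile_halfwidth` columns on
#' each side, with angular wrap) is scanned for its two strongest local
#' maxima separated by at least `min_gap` rows.  The inner maximum seeds
#' the luminal band, the outer the adventitial band.  Anchors where no
#' such pair exists are filled in from their neighbours; if more than
#' half the anchors fail, a detection-failure error names them.  Band
#' centres are interpolated linearly between anchors (periodic in angle)
#' and widened by `margin` rows on each side; overlapping LB/AB bands
#' are trimmed at the midpoint so the LB band stays strictly inside.
#'
#' @param map A [separability_map()].
#' @param n_anchors Number of anchor angles (default 8).
#' @param min_gap Minimum radial separation of the two seeds, rows.
#' @param margin Half-width of each search band, rows.
#' @param profile_halfwidth Columns averaged on each side of an anchor.
#' @return An object of class `search_area`: per-column integer vectors
#'   `lb_lo`, `lb_hi`, `ab_lo`, `ab_hi` and a data frame `seeds`.
#' @export
place_seeds <- function(map, n_anchors = 8, min_gap = 10, margin = 8,
                        profile_halfwidth = 2) {
  stopifnot(inherits(map, "separability_map"))
  v <- map$values
  n <- nrow(v); m <- ncol(v)
  if (m < 8L) stop_invalid("map must have at least 8 angular columns")
  check_count(n_anchors, "n_anchors")

  anchor_cols <- floor((seq_len(n_anchors) - 1) * m / n_anchors) + 1L
  lb_seed <- ab_seed <- rep(NA_real_, n_anchors)
  for (a in seq_len(n_anchors)) {
    cols <- ((anchor_cols[a] - 1 + seq(-profile_halfwidth, profile_halfwidth)) %% m) + 1L
    prof <- rowMeans(v[, cols, drop = FALSE])
    pk <- local_maxima(prof)
    if (length(pk) >= 2L) {
      pk <- pk[order(-prof[pk], pk)]
      r1 <- pk[1]
      partner <- pk[abs(pk - r1) >= min_gap]
      if (length(partner)) {
        r2 <- partner[1]
        lb_seed[a] <- min(r1, r2)
        ab_seed[a] <- max(r1, r2)
      }
    }
  }
  failed <- which(is.na(lb_seed))
  if (length(failed) > n_anchors / 2) {
    stop(errorCondition(
      sprintf("seed placement failed at anchors %s (columns %s): fewer than two separated separability maxima",
              paste(failed, collapse = ", "),
              paste(anchor_cols[failed], collapse = ", ")),
      class = c("ivus_detection_failure", "error")))
  }
  ok <- which(!is.na(lb_seed))
  if (length(failed)) {
    lb_seed[failed] <- interp_periodic(anchor_cols[ok], lb_seed[ok], m)[anchor_cols[failed]]
    ab_seed[failed] <- interp_periodic(anchor_cols[ok], ab_seed[ok], m)[anchor_cols[failed]]
  }

  lb_c <- interp_periodic(anchor_cols, lb_seed, m)
  ab_c <- interp_periodic(anchor_cols, ab_seed, m)
  lb_lo <- pmax(1L, as.integer(round(lb_c - margin)))
  lb_hi <- pmin(n,  as.integer(round(lb_c + margin)))
  ab_lo <- pmax(1L, as.integer(round(ab_c - margin)))
  ab_hi <- pmin(n,  as.integer(round(ab_c + margin)))
  # keep the luminal band strictly inside the adventitial band
  mid <- (lb_c + ab_c) / 2
  clash <- lb_hi >= ab_lo
  lb_hi[clash] <- pmax(lb_lo[clash], as.integer(floor(mid[clash])))
  ab_lo[clash] <- pmin(ab_hi[clash], as.integer(ceiling(mid[clash])) + 1L)

  structure(
    list(lb_lo = lb_lo, lb_hi = lb_hi, ab_lo = ab_lo, ab_hi = ab_hi,
         seeds = data.frame(anchor = seq_len(n_anchors),
                            column = anchor_cols,
                            lb_row = lb_seed, ab_row = ab_seed,
                            interpolated = seq_len(n_anchors) %in% failed)),
    class = "search_area")
}

# Indices of (plateau-tolerant) local maxima of a positive profile.
local_maxima <- function(prof) {
  n <- length(prof)
  if (n < 3L) return(integer(0))
  left <- c(-Inf, prof[-n])
  right <- c(prof[-1], -Inf)
  which(prof > 0 & prof >= left & prof > right)
}

#' Collect weighted boundary candidates inside the search bands
#'
#' Per boundary and per angular column, the `top_m` separability values
#' inside the search interval become candidates, weighted by their map
#' value; ties break towards smaller radius.  Columns with an empty
#' interval contribute nothing.
#'
#' @param map A [separability_map()].
#' @param area A [place_seeds()] result.
#' @param top_m Candidates kept per column per boundary (>= 1).
#' @return A data frame with columns `boundary` (`"LB"`/`"AB"`),
#'   `column`, `theta`, `radius`, `omega`, of class `candidate_set`.
#' @export
collect_candidates <- function(map, area, top_m = 3) {
  stopifnot(inherits(map, "separability_map"), inherits(area, "search_area"))
  check_count(top_m, "top_m")
  v <- map$values
  m <- ncol(v)
  one_boundary <- function(lo, hi, label) {
    res <- vector("list", m)
    for (j in seq_len(m)) {
      if (lo[j] > hi[j]) next
      rows <- lo[j]:hi[j]
      vals <- v[rows, j]
      keep <- order(-vals, rows)[seq_len(min(top_m, length(rows)))]
      res[[j]] <- data.frame(boundary = label, column = j,
                             theta = 2 * pi * (j - 1) / m,
                             radius = rows[keep], omega = vals[keep])
    }
    do.call(rbind, res)
  }
  out <- rbind(one_boundary(area$lb_lo, area$lb_hi, "LB"),
               one_boundary(area$ab_lo, area$ab_hi, "AB"))
  class(out) <- c("candidate_set", class(out))
  out
}

#' Fit a Takagi-Sugeno fuzzy model to boundary candidates
#'
#' Places `R` Gaussian membership functions at evenly-spaced centres on
#' `[0, 2*pi)` with common width `sigma = (2*pi/R) * overlap`, computed
#' on the periodic angular distance.  Each rule's linear consequent
#' `r = a_i * d + b_i` (with `d` the wrapped offset from the rule
#' centre) is fitted by weighted least squares over all candidates, each
#' weighted by its separability `omega` times its normalised membership
#' in the rule.  Rules whose normal equations are rank-deficient fall
#' back to the weighted mean radius of their support.
#'
#' @param candidates A [collect_candidates()] data frame (or any data
#'   frame with `theta`, `radius`, `omega`), typically for one boundary.
#' @param R Number of fuzzy rules (>= 2).
#' @param overlap Membership width as a fraction of the centre spacing.
#' @return An object of class `ts_fuzzy_model` with `centers`, `sigma`,
#'   `a`, `b`, `fallback`.
#' @export
fit_ts_model <- function(candidates, R = 8, overlap = 0.6) {
  check_count(R, "R")
  if (R < 2L) stop_invalid("R must be >= 2")
  theta <- candidates$theta
  r <- candidates$radius
  omega <- candidates$omega
  if (length(theta) < 3 * R) {
    stop_invalid(sprintf("need at least %d candidates for %d rules", 3 * R, R))
  }
  bins <- unique(floor((theta %% (2 * pi)) / (2 * pi) * 16))
  if (length(bins) < 8L) {
    stop_invalid("candidates must span at least half the angular range")
  }

  centers <- 2 * pi * (seq_len(R) - 1) / R
  sigma <- (2 * pi / R) * overlap
  delta <- outer(theta, centers, function(t, c) wrap_angle(t - c))
  mu <- exp(-delta^2 / (2 * sigma^2))
  mu_norm <- mu / rowSums(mu)

  a <- b <- numeric(R)
  fallback <- logical(R)
  r_mean <- stats::weighted.mean(r, pmax(omega, 1e-12))
  for (i in seq_len(R)) {
    w <- omega * mu_norm[, i]
    d <- delta[, i]
    sw <- sum(w); swx <- sum(w * d); swxx <- sum(w * d^2)
    swy <- sum(w * r); swxy <- sum(w * d * r)
    det <- sw * swxx - swx^2
    if (sw <= 1e-12 || det <= 1e-9 * max(sw * swxx, 1e-12)) {
      a[i] <- 0
      b[i] <- if (sw > 1e-12) swy / sw else r_mean
      fallback[i] <- TRUE
    } else {
      a[i] <- (sw * swxy - swx * swy) / det
      b[i] <- (swxx * swy - swx * swxy) / det
    }
  }
  structure(list(R = R, centers = centers, sigma = sigma, a = a, b = b,
                 fallback = fallback),
            class = "ts_fuzzy_model")
}

#' Evaluate a Takagi-Sugeno model at arbitrary angles
#'
#' @param model A [fit_ts_model()] result.
#' @param theta Angles in radians.
#' @return Inferred radii (rows), a convex combination of the rule
#'   consequents' outputs.
#' @export
ts_predict <- function(model, theta) {
  stopifnot(inherits(model, "ts_fuzzy_model"))
  delta <- outer(theta, model$centers, function(t, c) wrap_angle(t - c))
  mu <- exp(-delta^2 / (2 * model$sigma^2))
  cons <- sweep(delta, 2, model$a, `*`)
  cons <- sweep(cons, 2, model$b, `+`)
  rowSums(mu * cons) / rowSums(mu)
}

#' Sample a fitted boundary model on the polar grid
#'
#' Evaluates the model at each column's angle and clamps the result into
#' the radial extent.
#'
#' @param model A [fit_ts_model()] result.
#' @param n_angles Number of angular columns.
#' @param n_radii Radial extent used for clamping (optional).
#' @param label Curve label passed to [boundary_curve()].
#' @return A [boundary_curve()].
#' @export
infer_boundary <- function(model, n_angles, n_radii = NULL,
                           label = c("LB", "AB")) {
  check_count(n_angles, "n_angles")
  theta <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  r <- ts_predict(model, theta)
  if (!is.null(n_radii)) r <- pmin(pmax(r, 1), n_radii)
  boundary_curve(r, label = match.arg(label))
}

#' Detect the luminal and adventitial boundaries in a polar IVUS image
#'
#' Runs the full pipeline: anisotropic diffusion filtering, weighted
#' separability mapping, seed placement, candidate collection, and
#' Takagi-Sugeno fuzzy inference of the two boundary curves.  Columns
#' where the inferred curves cross are repaired by swapping, so the
#' luminal curve is strictly inside the adventitial one everywhere.
#' Returned radii refer to the A/B split plane of the separability
#' window (half a row above the best-scoring pixel row), which makes
#' the estimate unbiased on an ideal step edge.
#'
#' @param img A [polar_image()].
#' @param dparams A [diffusion_params()].
#' @param window A [separability_window()].
#' @param R Fuzzy rules per boundary.
#' @param mode Diffusion variant, `"modified"` (default) or `"normal"`.
#' @param n_anchors,min_gap,margin,top_m Seed/candidate settings, see
#'   [place_seeds()] and [collect_candidates()].
#' @param overlap Membership width fraction, see [fit_ts_model()].
#' @return A list of class `boundary_detection`: `lb` and `ab`
#'   ([boundary_curve()]s), plus `filtered`, `map`, `area`,
#'   `candidates`, `n_swapped`.
#' @export
detect_boundaries <- function(img, dparams = diffusion_params(),
                              window = separability_window(), R = 8,
                              mode = c("modified", "normal"),
                              n_anchors = 8, min_gap = 10, margin = 8,
                              top_m = 3, overlap = 0.6) {
  stopifnot(inherits(img, "polar_image"))
  mode <- match.arg(mode)
  filt <- run_diffusion(img, dparams, mode)
  map <- separability_map(filt, window, weighted = TRUE)
  area <- place_seeds(map, n_anchors = n_anchors, min_gap = min_gap,
                      margin = margin)
  cand <- collect_candidates(map, area, top_m = top_m)
  # Candidates live on pixel rows; the boundary itself is the A/B split
  # plane of the separability window, half a row above the evaluated
  # pixel, so the final curves are shifted by -0.5 rows.
  fit_one <- function(lbl) {
    cc <- cand[cand$boundary == lbl, ]
    model <- fit_ts_model(cc, R = R, overlap = overlap)
    r <- infer_boundary(model, img$n_angles, label = lbl) - 0.5
    boundary_curve(pmin(pmax(as.numeric(r), 0.5), img$n_radii), label = lbl)
  }
  lb <- fit_one("LB")
  ab <- fit_one("AB")
  bad <- which(lb >= ab)
  if (length(bad)) {
    lo <- pmin(lb[bad], ab[bad]); hi <- pmax(lb[bad], ab[bad])
    eq <- lo >= hi
    lo[eq] <- pmax(1, hi[eq] - 1e-6)
    lb[bad] <- lo; ab[bad] <- hi
  }
  structure(list(lb = boundary_curve(as.numeric(lb), "LB"),
                 ab = boundary_curve(as.numeric(ab), "AB"),
                 filtered = filt, map = map, area = area,
                 candidates = cand, n_swapped = length(bad)),
            class = "boundary_detection")
}

#' @export
print.boundary_detection <- function(x, ...) {
  cat(sprintf("<boundary_detection> %d angles; LB %.1f-%.1f, AB %.1f-%.1f rows (%d column(s) swapped)\n",
              length(x$lb), min(x$lb), max(x$lb), min(x$ab), max(x$ab),
              x$n_swapped))
  invisible(x)
}
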