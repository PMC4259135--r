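test_that("seeds land on the two ridges of a clean map", {
  map <- two_ridge_map()
  area <- place_seeds(map, n_anchors = 8, min_gap = 10, margin = 8)
  expect_equal(area$seeds$lb_row, rep(40, 8))
  expect_equal(area$seeds$ab_row, rep(80, 8))
  expect_true(all(area$lb_lo <= 40 & area$lb_hi >= 40))
  expect_true(all(area$ab_lo <= 80 & area$ab_hi >= 80))
  expect_true(all(area$lb_hi < area$ab_lo))
})

test_that("a single ridge raises a detection failure naming the anchors", {
  vals <- matrix(0, 128, 64)
  vals[50, ] <- 0.8
  map <- two_ridge_map()
  map$values <- vals
  err <- tryCatch(place_seeds(map), error = identity)
  expect_s3_class(err, "ivus_detection_failure")
  expect_match(conditionMessage(err), "anchors 1, 2")
})

test_that("anchors with ridges closer than the gap are interpolated from neighbours", {
  map <- two_ridge_map(r1 = 40, r2 = 80)
  # within anchor 3's aperture (column 17 +/- 2 of 64) replace the outer
  # ridge with one only 5 rows away from the inner ridge
  cols <- 15:19
  map$values[80, cols] <- 0
  map$values[45, cols] <- 0.9
  area <- place_seeds(map, min_gap = 10, margin = 8)
  expect_true(area$seeds$interpolated[3])
  expect_false(any(area$seeds$interpolated[-3]))
  expect_equal(area$seeds$ab_row[3], 80, tolerance = 1e-6)
})

test_that("candidate collection honours top_m, tie-breaks and empty intervals", {
  map <- two_ridge_map()
  area <- place_seeds(map)
  cand <- collect_candidates(map, area, top_m = 1)
  lb <- cand[cand$boundary == "LB", ]
  expect_equal(nrow(lb), 64)
  expect_equal(lb$radius, rep(40, 64))
  expect_equal(lb$omega, rep(0.6, 64))

  # all-zero map: tie-break toward the smallest radius of the interval
  map0 <- map
  map0$values[] <- 0
  c0 <- collect_candidates(map0, area, top_m = 1)
  expect_equal(c0$radius[c0$boundary == "LB"], area$lb_lo)
  expect_true(all(c0$omega == 0))

  # top_m larger than the interval keeps every interval pixel
  call <- collect_candidates(map, area, top_m = 1000)
  j1 <- call[call$boundary == "LB" & call$column == 1, ]
  expect_equal(sort(j1$radius), area$lb_lo[1]:area$lb_hi[1])
})

test_that("the T-S model reproduces constant and sinusoidal candidate sets", {
  m <- 96
  theta <- 2 * pi * (seq_len(m) - 1) / m
  const <- data.frame(theta = theta, radius = 60, omega = 1)
  fit <- fit_ts_model(const, R = 8)
  expect_equal(ts_predict(fit, theta), rep(60, m), tolerance = 1e-9)

  sine <- data.frame(theta = theta, radius = 60 + 10 * sin(theta), omega = 1)
  fit2 <- fit_ts_model(sine, R = 8)
  curve <- infer_boundary(fit2, m, label = "LB")
  expect_lt(max(abs(as.numeric(curve) - (60 + 10 * sin(theta)))), 1)
})

test_that("conflicting equal-weight candidates resolve to their weighted mean", {
  m <- 64
  theta <- 2 * pi * (seq_len(m) - 1) / m
  cand <- data.frame(theta = rep(theta, 2),
                     radius = rep(c(55, 65), each = m),
                     omega = 1)
  fit <- fit_ts_model(cand, R = 8)
  expect_equal(ts_predict(fit, theta), rep(60, m), tolerance = 1e-6)
})

test_that("inference is a convex combination of the rule consequents", {
  set.seed(31)
  for (rep in 1:10) {
    cand <- data.frame(theta = runif(60, 0, 2 * pi),
                       radius = runif(60, 20, 100),
                       omega = runif(60))
    fit <- fit_ts_model(cand, R = 6)
    theta <- seq(0, 2 * pi, length.out = 33)
    pred <- ts_predict(fit, theta)
    cons <- sapply(seq_len(6), function(i) {
      d <- ((theta - fit$centers[i] + pi) %% (2 * pi)) - pi
      fit$a[i] * d + fit$b[i]
    })
    expect_true(all(pred >= apply(cons, 1, min) - 1e-9))
    expect_true(all(pred <= apply(cons, 1, max) + 1e-9))
  }
})

test_that("up-weighting a candidate subset pulls the fit monotonically toward it", {
  m <- 64
  theta <- 2 * pi * (seq_len(m) - 1) / m
  lows <- data.frame(theta = theta, radius = 50, omega = 1)
  prev <- -Inf
  for (w2 in c(0.25, 0.5, 1, 2, 4)) {
    highs <- data.frame(theta = theta, radius = 70, omega = w2)
    fit <- fit_ts_model(rbind(lows, highs), R = 8)
    mid <- mean(ts_predict(fit, theta))
    expect_gt(mid, prev)
    prev <- mid
  }
  expect_lt(prev, 70)
})

test_that("model preconditions and fallbacks behave", {
  theta <- 2 * pi * (0:20) / 64          # only a third of the circle
  few <- data.frame(theta = theta, radius = 50, omega = 1)
  expect_error(fit_ts_model(few, R = 8), class = "ivus_invalid_argument")
  third <- data.frame(theta = 2 * pi * (0:30) / 80, radius = 50, omega = 1)
  expect_error(fit_ts_model(third, R = 8), class = "ivus_invalid_argument")
  # zero weights everywhere: every rule falls back to a mean radius
  m <- 64
  allz <- data.frame(theta = 2 * pi * (seq_len(m) - 1) / m, radius = 44,
                     omega = 0)
  fit <- fit_ts_model(allz, R = 4)
  expect_true(all(fit$fallback))
  expect_equal(ts_predict(fit, 1.3), 44, tolerance = 1e-9)
})

test_that("inferred curves are periodic across the angular seam", {
  m <- 96
  theta <- 2 * pi * (seq_len(m) - 1) / m
  sine <- data.frame(theta = theta, radius = 60 + 8 * cos(theta), omega = 1)
  fit <- fit_ts_model(sine, R = 8)
  expect_lt(abs(ts_predict(fit, 0) - ts_predict(fit, 2 * pi - 1e-6)), 0.05)
  curve <- infer_boundary(fit, m, n_radii = 128, label = "AB")
  expect_s3_class(curve, "boundary_curve")
  expect_equal(attr(curve, "label"), "AB")
})

test_that("detection recovers noise-free phantom boundaries within one row", {
  ph <- generate_phantom(phantom_spec(seed = 4, speckle_sigma = 0,
                                      blur_sigma = 0))
  det <- detect_boundaries(ph$image)
  expect_lt(max(abs(as.numeric(det$lb) - as.numeric(ph$lb))), 1)
  expect_lt(max(abs(as.numeric(det$ab) - as.numeric(ph$ab))), 1)
  expect_true(all(as.numeric(det$lb) < as.numeric(det$ab)))
})

test_that("detection on a uniform image fails with a detection error", {
  img <- polar_image(matrix(80, 64, 64))
  expect_error(detect_boundaries(img), class = "ivus_detection_failure")
})

test_that("fixed-seed phantoms yield bit-identical curves across runs", {
  ph1 <- generate_phantom(phantom_spec(seed = 99))
  ph2 <- generate_phantom(phantom_spec(seed = 99))
  expect_identical(ph1$image$pixels, ph2$image$pixels)
  d1 <- detect_boundaries(ph1$image)
  d2 <- detect_boundaries(ph2$image)
  expect_identical(as.numeric(d1$lb), as.numeric(d2$lb))
  expect_identical(as.numeric(d1$ab), as.numeric(d2$ab))
})
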