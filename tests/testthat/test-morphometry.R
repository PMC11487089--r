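make_record <- function(num_val = 2, den_val = 1, n = 32, bg = 0,
                        distance_mm = 0) {
  px <- matrix(0L, n, n)
  px[9:24, 9:24] <- 1L
  num <- matrix(bg, n, n); num[px == 1L] <- num_val + bg
  den <- matrix(bg, n, n); den[px == 1L] <- den_val + bg
  spheroid_record(label_mask(px), list(num = num, den = den),
                  distance_mm = distance_mm)
}

test_that("invasiveness index matches oracle and honors its invariances", {
  spec <- shape_spec(90, 0.25, c(6L), seed = 9L)
  phases <- dispersim:::shape_phases(spec)
  orc <- oracle_shape_metrics(90, 0.25, 6L, phases)
  mask <- make_spheroid_mask(spec)
  got <- invasiveness_index(mask)
  expect_equal(got, orc$invasiveness, tolerance = 0.02)

  # translation invariance: embed the same shape off-center
  big <- matrix(0L, 400, 400)
  px <- mask$pixels
  big[30 + seq_len(nrow(px)), 80 + seq_len(ncol(px))] <- px
  expect_equal(invasiveness_index(label_mask(big)), got,
               tolerance = 1e-9)

  # 90-degree rotation (exact on the lattice)
  rot <- label_mask(t(px)[ncol(px):1, ])
  expect_equal(invasiveness_index(rot), got, tolerance = 1e-9)

  # uniform scaling: same spec at twice the radius
  spec2 <- shape_spec(180, 0.25, c(6L), seed = 9L)
  got2 <- invasiveness_index(make_spheroid_mask(spec2))
  expect_equal(got2, got, tolerance = 0.02)
})

test_that("too-small or missing labels are rejected", {
  px <- matrix(0L, 20, 20); px[10, 10] <- 1L
  expect_error(invasiveness_index(label_mask(px)),
               class = "object_not_found")
  px2 <- matrix(0L, 20, 20)
  px2[5:15, 5:15] <- 1L
  expect_error(invasiveness_index(label_mask(px2), label = 2L),
               class = "object_not_found")
})

test_that("fluorescence ratio recovers constructed channel ratios", {
  expect_equal(fluorescence_ratio(make_record(1, 1), "num", "den"), 1)
  expect_equal(fluorescence_ratio(make_record(2, 1), "num", "den"), 2)
  # background subtraction: constant offset must not bias the ratio
  expect_equal(fluorescence_ratio(make_record(2, 1, bg = 50), "num", "den"),
               2)
  expect_error(fluorescence_ratio(make_record(1, 0), "num", "den"),
               class = "degenerate_signal")
  expect_error(fluorescence_ratio(make_record(), "num", "missing"),
               class = "input_error")
})

test_that("reporter ratios rise along a synthetic hypoxia gradient", {
  dists <- seq(1, 11, by = 2)
  slope_true <- 0.3
  ratios <- vapply(dists, function(d)
    fluorescence_ratio(make_record(1 + slope_true * d, 1,
                                   distance_mm = d), "num", "den"),
    numeric(1))
  fit <- gradient_fit(dists, ratios)
  expect_equal(fit$slope, slope_true, tolerance = 0.02)
  expect_gt(fit$r, 0.99)
})

test_that("Delaunay densities match the brute-force circumcircle oracle", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(8:16, 1)
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    pts <- point_set(x, y)
    tri <- delaunay(pts)
    orc <- oracle_delaunay(x, y)
    expect_equal(unname(tri), unname(orc))
    ld <- local_density(pts)
    expect_true(all(ld$density > 0))
  }
})

test_that("triangle areas tile the convex hull and scale as s^-2", {
  set.seed(8)
  pts <- point_set(runif(30, 0, 50), runif(30, 0, 50))
  ld <- local_density(pts)
  hull <- grDevices::chull(pts$x_um, pts$y_um)
  hull_area <- dispersim:::polygon_area(pts$x_um[hull], pts$y_um[hull])
  expect_equal(sum(ld$areas), hull_area, tolerance = 1e-9)

  s <- 3
  ld2 <- local_density(point_set(s * pts$x_um, s * pts$y_um))
  expect_equal(ld2$mean_density, ld$mean_density / s^2, tolerance = 1e-9)
})

test_that("degenerate point sets raise geometry errors", {
  expect_error(delaunay(point_set(c(0, 1), c(0, 0))),
               class = "geometry_error")
  expect_error(delaunay(point_set(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               class = "geometry_error")
})

test_that("density timecourse tracks dispersal and flags bad frames", {
  pts <- make_nuclei_points(25, box_um = c(60, 60), dispersion = 1,
                            seed = 3L)
  static <- density_timecourse(list(pts, pts, pts))
  expect_true(all(abs(diff(static$mean_density)) < 1e-12))

  # radial expansion by 10% per frame: densities decay as 1.1^(-2t)
  frames <- lapply(0:4, function(t)
    point_set(pts$x_um * 1.1^t, pts$y_um * 1.1^t))
  tc <- density_timecourse(frames)
  expect_equal(tc$mean_density,
               tc$mean_density[1] * 1.1^(-2 * (0:4)), tolerance = 1e-9)

  bad <- list(pts, point_set(c(0, 1, 2), c(0, 0, 0)))
  expect_error(density_timecourse(bad), class = "geometry_error")
  expect_error(density_timecourse(bad), "frame 2")
})

test_that("pH calibration round-trips anchors and interpolates linearly", {
  r <- c(0.8, 1.0, 1.2, 1.4, 1.6)
  ph <- c(7.8, 7.4, 7.0, 6.6, 6.2)   # linear map for the identity check
  curve <- calibrate_ph(r, ph)
  expect_equal(as.numeric(ph_from_ratio(curve, r)), ph)
  mid <- ph_from_ratio(curve, 1.1)
  expect_equal(as.numeric(mid), 7.2, tolerance = 1e-9)
  # clamped queries are flagged
  out <- ph_from_ratio(curve, c(0.5, 1.0, 2.0))
  expect_identical(attr(out, "clamped"), c(TRUE, FALSE, TRUE))
  expect_equal(as.numeric(out)[c(1, 3)], c(7.8, 6.2))

  expect_error(calibrate_ph(c(1, 1, 2), c(7, 7.2, 7.4)),
               class = "calibration_error")
  expect_error(calibrate_ph(c(1, 2, 3), c(7, 6, 8)),
               class = "calibration_error")
})

test_that("pH profiles are recovered from ratiometric images", {
  curve <- calibrate_ph(c(0.8, 1.0, 1.2, 1.4, 1.6),
                        c(7.8, 7.4, 7.0, 6.6, 6.2))
  d <- seq(0, 12, by = 0.25)
  flat_img <- make_gradient_image(
    gradient_profile(d, rep(1.0, length(d)), "ratio"), noise_sd = 0)
  prof <- estimate_ph_profile(flat_img, curve)
  expect_true(all(abs(prof$value - 7.4) < 1e-9))

  # consumer-like gradient: ratio rises with distance => pH falls
  grad_img <- make_gradient_image(
    gradient_profile(d, 1.0 + 0.04 * d, "ratio"), noise_sd = 0.01,
    seed = 4L)
  prof2 <- estimate_ph_profile(grad_img, curve)
  fit <- gradient_fit(prof2$distance_mm, prof2$value)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.001)
  # true slope: 0.04 ratio/mm * (-2 pH per ratio unit) = -0.08 pH/mm
  expect_equal(fit$slope, -0.08, tolerance = 0.05 * 0.08 + 0.01)

  expect_error(estimate_ph_profile(list(channels = list(green = NULL)),
                                   curve),
               class = "input_error")
})

test_that("degradation score counts the constructed dark fraction", {
  ref <- matrix(100, 40, 40)
  mask <- matrix(TRUE, 40, 40)
  expect_equal(degradation_score(ref, ref, mask), 0)

  # zero out 30% of the mask
  sample_img <- ref
  set.seed(12)
  idx <- sample(length(sample_img), round(0.3 * length(sample_img)))
  sample_img[idx] <- 0
  expect_equal(degradation_score(sample_img, ref, mask), 0.3,
               tolerance = 0.005)

  # distal-like fixture with many foci scores above proximal-like
  few <- ref; few[sample(length(few), 50)] <- 10
  many <- ref; many[sample(length(many), 400)] <- 10
  expect_gt(degradation_score(many, ref, mask),
            degradation_score(few, ref, mask))

  expect_error(degradation_score(ref, ref, matrix(FALSE, 40, 40)),
               class = "input_error")
})

test_that("DQ-collagen scoring mirrors the reporter ratio contract", {
  rec <- make_record(0, 1)
  names(rec$channels) <- c("dq_collagen", "membrane")
  expect_equal(dq_collagen_score(rec), 0)

  dists <- seq(1, 11, by = 2)
  vals <- vapply(dists, function(d) {
    r <- make_record(0.5 + 0.2 * d, 1, distance_mm = d)
    names(r$channels) <- c("dq_collagen", "membrane")
    dq_collagen_score(r)
  }, numeric(1))
  fit <- gradient_fit(dists, vals)
  expect_gt(fit$slope, 0)
  expect_equal(fit$slope, 0.2, tolerance = 0.02)
})

test_that("drug concentration estimates anchor to c0 and stay monotone", {
  pr <- make_decay_profile(c0 = 1, length_scale_mm = 8.3,
                           axis_length_mm = 12, step_mm = 0.5)
  est <- estimate_drug_concentration(pr, c0 = 150)
  expect_equal(est$value[1], 150)
  expect_true(all(diff(est$value) <= 0))
  # pointwise equality with the direct normalization
  expect_equal(est$value, 150 * pr$value / pr$value[1])

  # linear in c0 and invariant to intensity units
  est2 <- estimate_drug_concentration(pr, c0 = 300)
  expect_equal(est2$value, 2 * est$value)
  pr_scaled <- gradient_profile(pr$distance_mm, 7.3 * pr$value,
                                "intensity")
  est3 <- estimate_drug_concentration(pr_scaled, c0 = 150)
  expect_equal(est3$value, est$value)

  # noisy profile is isotonically monotonized and flagged
  set.seed(2)
  noisy <- gradient_profile(pr$distance_mm,
                            pr$value + rnorm(nrow(pr), sd = 0.02),
                            "intensity")
  estn <- estimate_drug_concentration(noisy, c0 = 150)
  expect_true(attr(estn, "monotonized"))
  expect_true(all(diff(estn$value) <= 1e-9))

  bad <- gradient_profile(c(0, 1), c(0, 0), "intensity")
  expect_error(estimate_drug_concentration(bad, 150),
               class = "degenerate_signal")
})

test_that("gradient_fit matches closed-form OLS and runs group tests", {
  x <- c(1, 2, 3, 4, 5)
  fit <- gradient_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r, 1)

  # known slope recovered within 2 SE; SE against the closed form
  set.seed(77)
  n <- 50; sdv <- 1
  xs <- runif(n, 0, 10)
  ys <- 0.5 * xs + rnorm(n, sd = sdv)
  f <- gradient_fit(xs, ys)
  se_closed <- sqrt(sum(residuals(f$fit)^2) / (n - 2) /
                      sum((xs - mean(xs))^2))
  expect_equal(f$slope_se, se_closed, tolerance = 1e-9)
  expect_lt(abs(f$slope - 0.5), 2 * f$slope_se)

  # permuted-y null: r distribution centered at zero
  set.seed(42)
  rs <- replicate(200, gradient_fit(xs, sample(ys))$r)
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(200))

  # group comparisons route to t test / Tukey
  g2 <- rep(c("a", "b"), each = 25)
  expect_s3_class(gradient_fit(xs, ys, g2)$group_test, "htest")
  g3 <- rep(c("a", "b", "c"), length.out = n)
  expect_s3_class(gradient_fit(xs, ys, g3)$group_test, "TukeyHSD")

  expect_error(gradient_fit(c(1, 1, 1), c(1, 2, 3)), class = "fit_error")
})

test_that("chamber regions use closed 2 mm and open 8 mm boundaries", {
  expect_identical(classify_region(c(0, 2.0, 2.001, 8.0, 8.001, 9.5)),
                   c("proximal", "proximal", "intermediate",
                     "intermediate", "distal", "distal"))
  expect_error(classify_region(-1), class = "input_error")
})
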