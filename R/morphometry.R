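#' Invasiveness index of a labelled spheroid
#'
#' The invasiveness index is the spheroid perimeter divided by the
#' perimeter of the circle with the same area — the inverse of circularity:
#' `P / (2 * sqrt(pi * A))`. It equals 1 for a circle and grows with
#' protrusive, ruffled outlines. Perimeter and area are measured on the
#' sub-pixel 0.5-level contour of the (lightly Gaussian-smoothed) binary
#' mask; naive pixel-edge perimeters overestimate the index by ~27% on
#' disks, which would break the index >= 1 contract.
#'
#' @param mask a [label_mask].
#' @param label which object label to measure (default 1).
#' @param min_pixels objects smaller than this are rejected (default 16;
#'   perimeter estimates are unstable below that).
#' @param smooth_sigma Gaussian pre-smoothing SD in pixels applied before
#'   contour extraction.
#' @return the dimensionless index (>= 1 up to ~2% discretization error).
#' @export
invasiveness_index <- function(mask, label = 1L, min_pixels = 16L,
                               smooth_sigma = 1.5) {
  if (!inherits(mask, "label_mask"))
    ds_stop("mask must be a label_mask", "invalid_spec")
  bin <- mask$pixels == label
  if (sum(bin) < min_pixels)
    ds_stop(sprintf("label %d absent or smaller than %d pixels",
                    label, min_pixels), "object_not_found")
  cm <- contour_metrics(bin, smooth_sigma)
  cm$perimeter / (2 * sqrt(pi * cm$area))
}

# gaussian-smooth a numeric matrix with a separable kernel, replicating
# edge rows/cols so the boundary is not darkened
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  pad <- ceiling(3 * sigma)
  g <- dnorm(seq(-pad, pad), sd = sigma)
  g <- g / sum(g)
  n <- nrow(img); m <- ncol(img)
  imp <- img[c(rep(1L, pad), seq_len(n), rep(n, pad)),
             c(rep(1L, pad), seq_len(m), rep(m, pad))]
  sm <- apply(imp, 2, function(v) stats::filter(v, g, sides = 2))
  sm <- t(apply(sm, 1, function(v) stats::filter(v, g, sides = 2)))
  sm[pad + seq_len(n), pad + seq_len(m)]
}

# sub-pixel perimeter/area of a binary object: smooth, then trace the
# 0.5-level with marching squares (grDevices::contourLines); the longest
# closed contour is taken as the outer boundary
contour_metrics <- function(bin, smooth_sigma = 1.5) {
  sm <- gauss_smooth(bin + 0, smooth_sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(sm)),
                                y = seq_len(ncol(sm)),
                                z = sm, levels = 0.5)
  if (length(cl) == 0L)
    ds_stop("no contour found at level 0.5", "object_not_found")
  lens <- vapply(cl, function(p) polygon_perimeter(p$x, p$y), numeric(1))
  p <- cl[[which.max(lens)]]
  list(perimeter = polygon_perimeter(p$x, p$y),
       area = polygon_area(p$x, p$y),
       contour = p)
}

#' Background-subtracted mean fluorescence ratio over a spheroid
#'
#' Per-spheroid reporter quantification: the mean of the numerator channel
#' over the mask divided by the mean of the denominator (constitutive)
#' channel, after subtracting each channel's background median (background =
#' pixels outside all labels). This is the normalization used to read
#' hypoxia-reporter intensity against a constitutive membrane label.
#'
#' @param record a [spheroid_record].
#' @param numerator_channel,denominator_channel channel names in the record.
#' @return the dimensionless ratio (negative numerator means are clamped at
#'   0 after background subtraction).
#' @export
fluorescence_ratio <- function(record, numerator_channel,
                               denominator_channel) {
  if (!inherits(record, "spheroid_record"))
    ds_stop("record must be a spheroid_record", "invalid_spec")
  for (ch in c(numerator_channel, denominator_channel))
    if (!ch %in% names(record$channels))
      ds_stop(sprintf("channel '%s' missing [%s]", ch, record$spheroid_id),
              "input_error")
  fg <- record$mask$pixels > 0
  if (!any(fg)) ds_stop("empty mask", "input_error")
  num <- record$channels[[numerator_channel]]
  den <- record$channels[[denominator_channel]]
  bg <- !fg
  bg_num <- if (any(bg)) stats::median(num[bg]) else 0
  bg_den <- if (any(bg)) stats::median(den[bg]) else 0
  m_num <- max(mean(num[fg]) - bg_num, 0)
  m_den <- mean(den[fg]) - bg_den
  if (m_den <= 0)
    ds_stop(sprintf("denominator signal not above background [%s]",
                    record$spheroid_id), "degenerate_signal")
  m_num / m_den
}

#' DQ-collagen degradation score
#'
#' Cleaved-collagen fluorescence normalized to the constitutive membrane
#' channel: a [fluorescence_ratio] with the cleaved-collagen channel as
#' numerator. Higher values mean more ECM cleavage.
#'
#' @param record a [spheroid_record].
#' @param cleaved_channel name of the cleaved-collagen (dequenched) channel.
#' @param reference_channel name of the constitutive channel.
#' @return dimensionless score (0 when the cleaved channel carries no
#'   signal).
#' @export
dq_collagen_score <- function(record, cleaved_channel = "dq_collagen",
                              reference_channel = "membrane") {
  fluorescence_ratio(record, cleaved_channel, reference_channel)
}

#' Local cell density from a Delaunay triangulation
#'
#' Triangulates the point cloud (nuclei centroids) and reports the inverse
#' area of each Delaunay triangle as the local cell density, plus the mean
#' density as the per-image summary.
#'
#' @param points a [point_set] (>= 3 non-collinear points).
#' @return a list with `triangles` (index matrix), `areas` (um^2),
#'   `density` (1/um^2 per triangle), and `mean_density`.
#' @export
local_density <- function(points) {
  tri <- delaunay(points)
  areas <- triangle_areas(points, tri)
  list(triangles = tri, areas = areas, density = 1 / areas,
       mean_density = mean(1 / areas))
}

#' Mean local density over a time-lapse
#'
#' Applies [local_density()] to each frame of nuclei positions; a
#' dispersing population (e.g. an ischemic spheroid) shows a decreasing
#' series, a static one a flat series.
#'
#' @param frames list of [point_set]s, one per frame.
#' @param t_min optional frame times in minutes.
#' @return data.frame with columns `frame`, `t_min`, `mean_density`.
#' @export
density_timecourse <- function(frames, t_min = NULL) {
  if (length(frames) < 2) ds_stop("need at least 2 frames", "input_error")
  if (is.null(t_min)) t_min <- seq_along(frames) - 1
  dens <- vapply(seq_along(frames), function(i) {
    tryCatch(local_density(frames[[i]])$mean_density,
             dispersim_error = function(e)
               ds_stop(sprintf("frame %d: %s", i, conditionMessage(e)),
                       "geometry_error"))
  }, numeric(1))
  data.frame(frame = seq_along(frames), t_min = t_min,
             mean_density = dens)
}

#' Calibrate the ratio-to-pH mapping
#'
#' Builds the monotone interpolant mapping a green/blue intensity ratio to
#' pH, from anchor measurements of media titrated with known lactic-acid
#' levels. A monotone piecewise-cubic (Hyman-filtered) spline is used so the
#' curve round-trips the anchors exactly and never oscillates; queries
#' outside the anchor range are clamped and flagged.
#'
#' @param anchor_ratios green/blue ratios at the anchors (strictly
#'   monotone, >= 3 values).
#' @param anchor_ph pH at each anchor (monotone in the opposite or same
#'   direction, as measured).
#' @return an object of class `calibration_curve`; evaluate it with
#'   [ph_from_ratio()].
#' @export
calibrate_ph <- function(anchor_ratios, anchor_ph) {
  if (length(anchor_ratios) < 3 ||
      length(anchor_ratios) != length(anchor_ph))
    ds_stop("need >= 3 matched anchors", "calibration_error")
  o <- order(anchor_ratios)
  r <- anchor_ratios[o]; p <- anchor_ph[o]
  if (any(diff(r) <= 0))
    ds_stop("anchor ratios must be strictly monotone", "calibration_error")
  if (!(all(diff(p) > 0) || all(diff(p) < 0)))
    ds_stop("anchor pH must be monotone in ratio", "calibration_error")
  structure(list(ratio = r, ph = p,
                 fun = stats::splinefun(r, p, method = "hyman")),
            class = "calibration_curve")
}

#' Evaluate a pH calibration curve
#'
#' @param curve a [calibrate_ph()] result.
#' @param ratio green/blue ratios to convert.
#' @return pH values; out-of-range ratios are clamped to the anchor range
#'   and flagged in the `"clamped"` attribute (logical vector).
#' @export
ph_from_ratio <- function(curve, ratio) {
  if (!inherits(curve, "calibration_curve"))
    ds_stop("curve must be a calibration_curve", "invalid_spec")
  lo <- min(curve$ratio); hi <- max(curve$ratio)
  clamped <- ratio < lo | ratio > hi
  out <- curve$fun(pmin(pmax(ratio, lo), hi))
  attr(out, "clamped") <- clamped
  out
}

#' Estimate an extracellular pH profile from a ratiometric image
#'
#' Bins a two-channel gradient image along the chamber axis, takes the
#' green/blue mean-intensity ratio per distance bin, and maps it through a
#' [calibration_curve] to pH.
#'
#' @param image a `gradient_image` (see [make_gradient_image()]) or a list
#'   with `channels$green`, `channels$blue` and `px_per_mm`.
#' @param curve a [calibration_curve].
#' @param bin_mm distance bin width in mm (default 0.5).
#' @return a [gradient_profile] of pH vs bin-center distance; bins whose
#'   ratio fell outside the calibration range are flagged in the
#'   `"clamped"` attribute.
#' @export
estimate_ph_profile <- function(image, curve, bin_mm = 0.5) {
  for (ch in c("green", "blue"))
    if (is.null(image$channels[[ch]]))
      ds_stop(sprintf("channel '%s' missing", ch), "input_error")
  ratio <- ratio_profile(image, bin_mm)
  ph <- ph_from_ratio(curve, ratio$value)
  out <- gradient_profile(ratio$distance_mm, as.numeric(ph), "pH")
  attr(out, "clamped") <- attr(ph, "clamped")
  out
}

# per-bin green/blue mean-intensity ratio along the image x axis
ratio_profile <- function(image, bin_mm = 0.5) {
  n_cols <- ncol(image$channels$green)
  d <- (seq_len(n_cols) - 0.5) / image$px_per_mm
  bins <- floor(d / bin_mm)
  g <- tapply(colMeans(image$channels$green), bins, mean)
  b <- tapply(colMeans(image$channels$blue), bins, mean)
  centers <- (as.numeric(names(g)) + 0.5) * bin_mm
  gradient_profile(centers, as.numeric(g / b), "ratio")
}

#' Fraction of a mask showing fluorescence loss
#'
#' ECM-degradation scoring for the fluorescent-gelatin assay: the fraction
#' of the mask area whose sample intensity falls below a set fraction of
#' the co-registered reference intensity at the same pixel (degradation
#' foci are local dark spots on the gelatin).
#'
#' @param sample_image,reference_image co-registered numeric matrices.
#' @param mask logical matrix (or [label_mask]) selecting the scored area.
#' @param threshold_frac intensity fraction below which a pixel counts as
#'   degraded (default 0.5).
#' @return fraction in `[0, 1]`.
#' @export
degradation_score <- function(sample_image, reference_image, mask,
                              threshold_frac = 0.5) {
  if (inherits(mask, "label_mask")) mask <- mask$pixels > 0
  if (!any(mask)) ds_stop("empty mask", "input_error")
  if (!identical(dim(sample_image), dim(reference_image)) ||
      !identical(dim(sample_image), dim(mask)))
    ds_stop("images and mask must share dimensions", "input_error")
  if (mean(reference_image[mask]) <= 0)
    ds_stop("reference signal is not positive", "degenerate_signal")
  mean(sample_image[mask] < threshold_frac * reference_image[mask])
}

#' Estimate a drug concentration profile from staining intensity
#'
#' Converts a fluorescence-intensity profile (e.g. fluorophore-conjugated
#' Taxol bound to microtubules, a proxy for local drug level) into absolute
#' concentration by anchoring the proximal end to the known source
#' concentration: `c(d) = c0 * I(d) / I(0)`. If noise makes the result
#' non-monotone it is projected onto the nearest non-increasing profile
#' (isotonic regression) and flagged.
#'
#' @param profile a [gradient_profile] of intensities.
#' @param c0 source concentration (value at distance 0), e.g. nM.
#' @return a [gradient_profile] of concentrations with the same distances;
#'   attribute `"monotonized"` says whether the isotonic projection
#'   changed anything.
#' @export
estimate_drug_concentration <- function(profile, c0) {
  if (!inherits(profile, "gradient_profile"))
    ds_stop("profile must be a gradient_profile", "invalid_spec")
  if (c0 <= 0) ds_stop("c0 must be > 0", "input_error")
  i0 <- profile$value[which.min(profile$distance_mm)]
  if (i0 <= 0) ds_stop("source intensity must be > 0", "degenerate_signal")
  conc <- c0 * profile$value / i0
  mono <- FALSE
  if (is.unsorted(rev(conc))) {   # not non-increasing
    conc <- -stats::isoreg(profile$distance_mm, -conc)$yf
    mono <- TRUE
  }
  out <- gradient_profile(profile$distance_mm, conc, "concentration_nM")
  attr(out, "monotonized") <- mono
  out
}

#' Linear fit of a metric against chamber distance
#'
#' Ordinary least-squares line of `value ~ distance` with the Pearson
#' correlation, the standard gradient-vs-distance summary. When group
#' labels are supplied the groups are also compared on the metric: two
#' groups by a two-tailed t test, three or more by one-way ANOVA followed
#' by Tukey's honest significant differences (Tukey–Kramer for unbalanced
#' groups).
#'
#' @param distance_mm numeric distances (>= 3 points, not all equal).
#' @param value metric values.
#' @param group optional group labels (factor or character).
#' @return a list of class `gradient_fit` with `slope`, `intercept`,
#'   `slope_se`, `r` (Pearson), `p_value` (of the correlation), `fit` (the
#'   `lm` object), and when groups are given `group_test` (htest or
#'   TukeyHSD).
#' @export
gradient_fit <- function(distance_mm, value, group = NULL) {
  if (length(distance_mm) < 3)
    ds_stop("need at least 3 points", "fit_error")
  if (length(distance_mm) != length(value))
    ds_stop("distance and value lengths differ", "fit_error")
  if (stats::var(distance_mm) == 0)
    ds_stop("distances are all equal", "fit_error")
  fit <- stats::lm(value ~ distance_mm)
  ct <- stats::cor.test(distance_mm, value)
  # summary.lm warns on numerically perfect fits (exact lines in tests)
  out <- list(slope = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              slope_se = suppressWarnings(summary(fit)$coefficients[2, 2]),
              r = unname(ct$estimate), p_value = ct$p.value, fit = fit)
  if (!is.null(group)) {
    group <- factor(group)
    if (nlevels(group) == 2) {
      out$group_test <- stats::t.test(value ~ group)
    } else if (nlevels(group) >= 3) {
      out$group_test <- stats::TukeyHSD(stats::aov(value ~ group))
    }
  }
  class(out) <- "gradient_fit"
  out
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("<gradient_fit> slope %.4g (SE %.3g), intercept %.4g, r = %.3f, p = %.3g\n",
              x$slope, x$slope_se, x$intercept, x$r, x$p_value))
  invisible(x)
}

#' Classify chamber position into proximal / intermediate / distal
#'
#' Spheroids at most 2 mm from the chamber opening are proximal
#' (well-nurtured), those further than 8 mm are distal (ischemic), the rest
#' intermediate. Boundaries are closed at 2 mm and open at 8 mm.
#'
#' @param distance_mm non-negative distances.
#' @return character vector in `{"proximal", "intermediate", "distal"}`.
#' @export
classify_region <- function(distance_mm) {
  if (any(is.na(distance_mm)) || any(distance_mm < 0))
    ds_stop("distances must be non-negative", "input_error")
  ifelse(distance_mm <= 2, "proximal",
         ifelse(distance_mm > 8, "distal", "intermediate"))
}
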