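#' Spheroid shape specification
#'
#' Describes a star-convex spheroid outline: a base circle of radius
#' `radius_px` whose boundary is modulated by sinusoidal "ruffles",
#' `r(theta) = R * (1 + A * sum_k sin(k*theta + phi_k))` over the requested
#' angular modes. Amplitude 0 gives a smooth disk (the morphology of
#' well-nurtured spheroids); larger amplitudes give the ruffled, protrusive
#' outlines typical of ischemic spheroids. Mode phases are drawn from the
#' seeded generator so one seed defines a reproducible shape family.
#'
#' @param radius_px base radius in pixels (> 0).
#' @param ruffle_amplitude ruffle amplitude as a fraction of the radius, in
#'   `[0, 1)`. With several modes the worst-case total modulation is
#'   `amplitude * length(modes)`; the boundary is checked to stay positive.
#' @param ruffle_modes integer angular frequencies (each >= 2).
#' @param pixel_size_um physical pixel size, um/pixel.
#' @param seed integer seed for the mode phases.
#' @return an object of class `shape_spec`.
#' @export
shape_spec <- function(radius_px, ruffle_amplitude = 0,
                       ruffle_modes = integer(), pixel_size_um = 1,
                       seed = 1L) {
  if (!is.numeric(radius_px) || radius_px <= 0)
    ds_stop("radius_px must be positive", "invalid_spec")
  if (ruffle_amplitude < 0 || ruffle_amplitude >= 1)
    ds_stop("ruffle_amplitude must be in [0, 1)", "invalid_spec")
  if (length(ruffle_modes) && any(ruffle_modes < 2 |
                                  ruffle_modes != round(ruffle_modes)))
    ds_stop("ruffle_modes must be integers >= 2", "invalid_spec")
  if (ruffle_amplitude > 0 && length(ruffle_modes) == 0L)
    ds_stop("ruffle_modes required when amplitude > 0", "invalid_spec")
  structure(list(radius_px = radius_px,
                 ruffle_amplitude = ruffle_amplitude,
                 ruffle_modes = as.integer(ruffle_modes),
                 pixel_size_um = pixel_size_um,
                 seed = as.integer(seed)),
            class = "shape_spec")
}

# analytic boundary radius r(theta) for a spec with given phases
shape_radius <- function(spec, theta, phases) {
  r <- rep(1, length(theta))
  if (spec$ruffle_amplitude > 0) {
    for (i in seq_along(spec$ruffle_modes))
      r <- r + spec$ruffle_amplitude *
        sin(spec$ruffle_modes[i] * theta + phases[i])
  }
  spec$radius_px * r
}

shape_phases <- function(spec) {
  if (length(spec$ruffle_modes) == 0L) return(numeric())
  with_seed(spec$seed, runif(length(spec$ruffle_modes), 0, 2 * pi))
}

#' Rasterize a spheroid mask from a shape specification
#'
#' Renders the analytic star-convex boundary of a [shape_spec] onto an
#' integer canvas as label 1 over background 0. The canvas is sized to
#' contain the maximal radius with a margin unless given explicitly.
#'
#' @param spec a [shape_spec].
#' @param canvas_px optional canvas side length in pixels.
#' @return a [label_mask] with a single foreground label 1.
#' @export
make_spheroid_mask <- function(spec, canvas_px = NULL) {
  if (!inherits(spec, "shape_spec"))
    ds_stop("spec must be a shape_spec", "invalid_spec")
  phases <- shape_phases(spec)
  # guard the star-convex contract: boundary must stay strictly positive
  th <- seq(0, 2 * pi, length.out = 3600)
  if (min(shape_radius(spec, th, phases)) <= 0)
    ds_stop("ruffle amplitude too large: boundary radius reaches zero",
            "invalid_spec")
  rmax <- spec$radius_px * (1 + spec$ruffle_amplitude *
                              max(1, length(spec$ruffle_modes)))
  if (is.null(canvas_px)) canvas_px <- 2L * ceiling(rmax) + 17L
  if (canvas_px < 2 * rmax + 4)
    ds_stop("canvas too small to contain the shape", "invalid_spec")
  cx <- (canvas_px + 1) / 2
  xs <- seq_len(canvas_px) - cx
  dx <- matrix(xs, canvas_px, canvas_px, byrow = TRUE)
  dy <- matrix(xs, canvas_px, canvas_px)
  theta <- atan2(dy, dx)
  inside <- sqrt(dx^2 + dy^2) <= shape_radius(spec, theta, phases)
  label_mask(matrix(as.integer(inside), canvas_px, canvas_px),
             pixel_size_um = spec$pixel_size_um)
}

#' Generate a nuclei point cloud
#'
#' Emulates the H2B-labelled nuclei used for local-density estimation: a
#' regular grid filling a rectangular field, optionally jittered by
#' isotropic Gaussian noise. Dispersion 0 returns the exact grid.
#'
#' @param n number of points (>= 3).
#' @param box_um field size, `c(width, height)` in um.
#' @param dispersion standard deviation of the jitter in um (>= 0).
#' @param seed integer seed.
#' @return a [point_set] of `n` points.
#' @export
make_nuclei_points <- function(n, box_um = c(100, 100), dispersion = 0,
                               seed = 1L) {
  if (n < 3) ds_stop("need at least 3 points", "invalid_spec")
  if (dispersion < 0) ds_stop("dispersion must be >= 0", "invalid_spec")
  nx <- ceiling(sqrt(n * box_um[1] / box_um[2]))
  ny <- ceiling(n / nx)
  gx <- (seq_len(nx) - 0.5) * box_um[1] / nx
  gy <- (seq_len(ny) - 0.5) * box_um[2] / ny
  pts <- expand.grid(x_um = gx, y_um = gy)[seq_len(n), ]
  if (dispersion > 0) {
    jit <- with_seed(seed, matrix(rnorm(2 * n, sd = dispersion), ncol = 2))
    pts$x_um <- pts$x_um + jit[, 1]
    pts$y_um <- pts$y_um + jit[, 2]
  }
  point_set(pts$x_um, pts$y_um)
}

#' Random-walk specification for synthetic cell tracks
#'
#' Defines an ensemble of 2D tracks at the imaging cadence of the study
#' (frames every 15–30 min over up to 24–72 h). Four kinematic models cover
#' the regimes seen in tracked tumor cells: `brownian` (uncorrelated
#' Gaussian steps; diffusive, MSD exponent 1), `ballistic` (straight motion;
#' exponent 2), `persistent` (heading decorrelates over
#' `persistence_time_min`, giving the Fuerth crossover from ballistic to
#' diffusive), and `biased` (brownian plus a constant drift per step).
#'
#' @param model one of `"brownian"`, `"ballistic"`, `"persistent"`,
#'   `"biased"`.
#' @param n_tracks number of tracks.
#' @param n_steps number of displacement steps per track (>= 2); each track
#'   has `n_steps + 1` samples.
#' @param dt_min frame interval in minutes (default 15).
#' @param step_scale_um per-step displacement scale in um (> 0): the
#'   per-coordinate Gaussian SD for brownian/biased steps, the constant step
#'   length for ballistic/persistent.
#' @param persistence_time_min directional persistence time (persistent
#'   model only).
#' @param bias_vector_um constant drift per step, `c(dx, dy)` um (biased
#'   model only).
#' @param seed integer seed.
#' @return an object of class `walk_spec`.
#' @export
walk_spec <- function(model, n_tracks, n_steps, dt_min = 15,
                      step_scale_um = 2, persistence_time_min = NULL,
                      bias_vector_um = NULL, seed = 1L) {
  models <- c("brownian", "ballistic", "persistent", "biased")
  if (!is.character(model) || !(model %in% models))
    ds_stop(sprintf("unknown walk model '%s'", paste(model, collapse = "/")),
            "invalid_spec")
  if (n_steps < 2) ds_stop("n_steps must be >= 2", "invalid_spec")
  if (step_scale_um <= 0) ds_stop("step_scale_um must be > 0", "invalid_spec")
  if (model == "persistent" &&
      (is.null(persistence_time_min) || persistence_time_min <= 0))
    ds_stop("persistent model needs persistence_time_min > 0", "invalid_spec")
  if (model == "biased" &&
      (is.null(bias_vector_um) || length(bias_vector_um) != 2))
    ds_stop("biased model needs a 2-vector bias_vector_um", "invalid_spec")
  structure(list(model = model, n_tracks = as.integer(n_tracks),
                 n_steps = as.integer(n_steps), dt_min = dt_min,
                 step_scale_um = step_scale_um,
                 persistence_time_min = persistence_time_min,
                 bias_vector_um = bias_vector_um,
                 seed = as.integer(seed)),
            class = "walk_spec")
}

#' Generate synthetic cell tracks
#'
#' Draws the ensemble described by a [walk_spec]. All tracks start at the
#' origin; positions are in um and times in minutes. For the persistent
#' model the heading performs a wrapped-Gaussian rotation each step with
#' turn SD `sqrt(2 * dt / P)`, so that the direction autocorrelation decays
#' as `exp(-dt/P)` and the ensemble MSD follows the classical
#' persistent-random-walk (Fuerth) form.
#'
#' @param spec a [walk_spec].
#' @return a [track_set].
#' @export
make_tracks <- function(spec) {
  if (!inherits(spec, "walk_spec"))
    ds_stop("spec must be a walk_spec", "invalid_spec")
  n <- spec$n_tracks; m <- spec$n_steps; s <- spec$step_scale_um
  steps <- with_seed(spec$seed, {
    switch(spec$model,
      brownian = list(dx = matrix(rnorm(n * m, sd = s), m, n),
                      dy = matrix(rnorm(n * m, sd = s), m, n)),
      ballistic = {
        th <- runif(n, 0, 2 * pi)
        list(dx = matrix(s * cos(th), m, n, byrow = TRUE),
             dy = matrix(s * sin(th), m, n, byrow = TRUE))
      },
      persistent = {
        sd_turn <- sqrt(2 * spec$dt_min / spec$persistence_time_min)
        th0 <- runif(n, 0, 2 * pi)
        turns <- matrix(rnorm(n * m, sd = sd_turn), m, n)
        th <- apply(rbind(th0, turns[-m, , drop = FALSE]), 2, cumsum)
        list(dx = s * cos(th), dy = s * sin(th))
      },
      biased = list(
        dx = matrix(rnorm(n * m, sd = s), m, n) + spec$bias_vector_um[1],
        dy = matrix(rnorm(n * m, sd = s), m, n) + spec$bias_vector_um[2]))
  })
  x <- rbind(0, apply(steps$dx, 2, cumsum))
  y <- rbind(0, apply(steps$dy, 2, cumsum))
  df <- data.frame(
    track_id = rep(seq_len(n), each = m + 1L),
    frame = rep(seq_len(m + 1L), times = n),
    t_min = rep((0:m) * spec$dt_min, times = n),
    x_um = as.vector(x), y_um = as.vector(y))
  track_set(df, dt_min = spec$dt_min)
}

#' Exponential decay profile
#'
#' Concentration-equivalent intensity decaying along the chamber axis,
#' `c(d) = c0 * exp(-d / length_scale)`: the shape used to emulate passive
#' drug (e.g. fluorophore-conjugated Taxol) diffusion profiles.
#'
#' @param c0 value at distance 0 (> 0), e.g. source concentration in nM.
#' @param length_scale_mm decay length (> 0).
#' @param axis_length_mm extent of the profile (> 0).
#' @param step_mm distance sampling step.
#' @param value_kind label for the value axis.
#' @return a [gradient_profile], monotone decreasing with `value[1] = c0`
#'   at distance 0.
#' @export
make_decay_profile <- function(c0, length_scale_mm, axis_length_mm = 12,
                               step_mm = 0.5, value_kind = "intensity") {
  if (c0 <= 0) ds_stop("c0 must be > 0", "invalid_spec")
  if (length_scale_mm <= 0)
    ds_stop("length_scale_mm must be > 0", "invalid_spec")
  d <- seq(0, axis_length_mm, by = step_mm)
  gradient_profile(d, c0 * exp(-d / length_scale_mm), value_kind)
}

#' Synthesize a two-channel ratiometric gradient image
#'
#' Builds a green/blue image pair whose per-column intensity ratio follows a
#' [gradient_profile] along the chamber axis (x), emulating phenol-red
#' ratiometric pH imaging. The gradient is one-dimensional along the
#' chamber, so a single row profile is repeated across the short axis; the
#' denominator channel is flat at `base_intensity` and i.i.d. Gaussian noise
#' of SD `noise_sd` (in ratio units) is added to the numerator.
#'
#' @param profile a [gradient_profile] of the target green/blue ratio,
#'   covering `[0, axis_length_mm]`.
#' @param axis_length_mm imaged axis length, mm.
#' @param px_per_mm pixels per mm along the axis.
#' @param n_rows image height in pixels.
#' @param noise_sd Gaussian noise SD in ratio units.
#' @param base_intensity denominator (blue) intensity level.
#' @param seed integer seed.
#' @return a list of class `gradient_image` with elements `channels`
#'   (named matrices `green`, `blue`), `px_per_mm`, and `axis_length_mm`.
#' @export
make_gradient_image <- function(profile, axis_length_mm = 12,
                                px_per_mm = 20, n_rows = 16, noise_sd = 0,
                                base_intensity = 100, seed = 1L) {
  if (!inherits(profile, "gradient_profile"))
    ds_stop("profile must be a gradient_profile", "invalid_spec")
  if (min(profile$distance_mm) > 0 ||
      max(profile$distance_mm) < axis_length_mm)
    ds_stop("profile must cover [0, axis_length_mm]", "invalid_spec")
  n_cols <- as.integer(round(axis_length_mm * px_per_mm))
  d <- (seq_len(n_cols) - 0.5) / px_per_mm
  ratio <- stats::approx(profile$distance_mm, profile$value, xout = d)$y
  green <- matrix(base_intensity * ratio, n_rows, n_cols, byrow = TRUE)
  if (noise_sd > 0)
    green <- green + with_seed(seed,
      matrix(rnorm(n_rows * n_cols, sd = base_intensity * noise_sd),
             n_rows, n_cols))
  blue <- matrix(base_intensity, n_rows, n_cols)
  structure(list(channels = list(green = green, blue = blue),
                 px_per_mm = px_per_mm, axis_length_mm = axis_length_mm,
                 seed = as.integer(seed)),
            class = "gradient_image")
}
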