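# per-track access helpers --------------------------------------------------

check_track <- function(track) {
  if (nrow(track) < 2)
    ds_stop("track needs at least 2 samples", "track_integrity")
  if (any(diff(track$t_min) <= 0))
    ds_stop("track times must be strictly increasing", "track_integrity")
  invisible(track)
}

#' Instantaneous speeds along a track
#'
#' Finite-difference speed `|dposition| / dt` for each consecutive sample
#' pair.
#'
#' @param track one track: data.frame with `t_min`, `x_um`, `y_um`.
#' @return numeric vector of length `nrow(track) - 1`, in um/min.
#' @export
instantaneous_speeds <- function(track) {
  check_track(track)
  sqrt(diff(track$x_um)^2 + diff(track$y_um)^2) / diff(track$t_min)
}

#' Net displacement of a track
#'
#' Straight-line distance between the last and first positions, in um.
#'
#' @param track one track.
#' @return scalar, um.
#' @export
net_displacement <- function(track) {
  check_track(track)
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 +
         (track$y_um[n] - track$y_um[1])^2)
}

#' Total path length of a track
#'
#' Sum of the step lengths; always at least the net displacement.
#'
#' @param track one track.
#' @return scalar, um.
#' @export
path_length <- function(track) {
  check_track(track)
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Directional persistence of a track
#'
#' Net displacement divided by total path length: 1 for straight motion, 0
#' for a closed loop. Undefined (flagged `NA`) for a track that never
#' moves.
#'
#' @param track one track.
#' @return scalar in `[0, 1]`, or `NA` with attribute `"reason"` when the
#'   path length is zero.
#' @export
persistence <- function(track) {
  p <- path_length(track)
  if (p == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero path length"
    return(out)
  }
  net_displacement(track) / p
}

#' Classify runner cells by net displacement
#'
#' A runner is a cell whose net displacement reaches the threshold
#' (inclusive by default: "50 um or more").
#'
#' @param tracks a [track_set].
#' @param threshold_um displacement threshold (default 50).
#' @param strict if `TRUE`, use a strict `>` rule instead of `>=`.
#' @return list with `per_track` (data.frame `track_id`, `net_um`,
#'   `runner`), `count`, and `fraction`.
#' @export
classify_runners <- function(tracks, threshold_um = 50, strict = FALSE) {
  if (threshold_um <= 0) ds_stop("threshold must be > 0", "invalid_spec")
  tl <- track_list(tracks)
  if (length(tl) == 0L) ds_stop("empty track set", "input_error")
  net <- vapply(tl, net_displacement, numeric(1))
  run <- if (strict) net > threshold_um else net >= threshold_um
  list(per_track = data.frame(track_id = names(tl), net_um = unname(net),
                              runner = unname(run), row.names = NULL),
       count = sum(run), fraction = mean(run))
}

#' Runner fraction as a function of threshold
#'
#' Sweep of [classify_runners()] over displacement thresholds, used to ask
#' whether a conclusion (e.g. "twice as many runners") depends on the
#' arbitrary cutoff. The fraction is monotone non-increasing in the
#' threshold.
#'
#' @param tracks a [track_set].
#' @param thresholds_um numeric vector of thresholds.
#' @param strict passed to [classify_runners()].
#' @return data.frame `threshold_um`, `fraction`.
#' @export
runner_sweep <- function(tracks, thresholds_um = seq(10, 150, by = 10),
                         strict = FALSE) {
  net <- vapply(track_list(tracks), net_displacement, numeric(1))
  frac <- vapply(thresholds_um, function(th)
    if (strict) mean(net > th) else mean(net >= th), numeric(1))
  data.frame(threshold_um = thresholds_um, fraction = frac)
}

# per-track sums of squared displacement per lag (time-averaged over all
# start times), honoring frame gaps. Returns S (sum) and N (pair count)
# matrices [track x lag].
msd_track_sums <- function(tl, lags) {
  S <- matrix(0, length(tl), length(lags))
  N <- matrix(0L, length(tl), length(lags))
  for (i in seq_along(tl)) {
    tr <- tl[[i]]
    fr <- tr$frame
    pos <- cbind(tr$x_um, tr$y_um)
    idx <- rep(NA_integer_, max(fr) - min(fr) + 1L)
    idx[fr - min(fr) + 1L] <- seq_along(fr)
    for (k in seq_along(lags)) {
      lag <- lags[k]
      if (lag >= length(idx)) next
      a <- idx[seq_len(length(idx) - lag)]
      b <- idx[seq_len(length(idx) - lag) + lag]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        d2 <- rowSums((pos[b[ok], , drop = FALSE] -
                         pos[a[ok], , drop = FALSE])^2)
        S[i, k] <- sum(d2)
        N[i, k] <- length(d2)
      }
    }
  }
  list(S = S, N = N)
}

#' Mean-squared displacement of a track ensemble
#'
#' Computes `MSD(tau)` either time-averaged and pooled over tracks (every
#' admissible start time of every track contributes one pair; the default
#' and the estimator that stabilizes long-lag noise) or as the ensemble
#' MSD from each track's origin. The maximum lag is capped at a quarter of
#' the track duration. Tracks missing more than `max_missing_frac` of
#' their frames are excluded from pooling (flagged in the result).
#'
#' @param tracks a [track_set].
#' @param scheme `"time_averaged_pooled"` or `"ensemble"`.
#' @param max_lag_frac cap on the lag range as a fraction of track length
#'   (default 1/4).
#' @param max_missing_frac gap tolerance per track (default 0.1).
#' @return an object of class `msd_curve`: data.frame `lag`, `lag_min`,
#'   `msd_um2`, `n_pairs`, with the per-track sums kept as attributes for
#'   bootstrap resampling.
#' @export
msd <- function(tracks, scheme = c("time_averaged_pooled", "ensemble"),
                max_lag_frac = 0.25, max_missing_frac = 0.1) {
  scheme <- match.arg(scheme)
  tl <- track_list(tracks)
  n_frames <- vapply(tl, function(tr)
    max(tr$frame) - min(tr$frame) + 1L, integer(1))
  missing_frac <- 1 - vapply(tl, nrow, integer(1)) / n_frames
  eligible <- missing_frac <= max_missing_frac
  if (!any(eligible))
    ds_stop("no eligible tracks (too many missing frames)", "input_error")
  tl <- tl[eligible]
  dt <- attr(tracks, "dt_min")
  max_lag <- max(1L, floor(max(n_frames[eligible] - 1L) * max_lag_frac))
  lags <- seq_len(max_lag)
  if (scheme == "time_averaged_pooled") {
    ts_sums <- msd_track_sums(tl, lags)
  } else {
    # ensemble: only displacements from each track's first sample
    S <- matrix(0, length(tl), length(lags))
    N <- matrix(0L, length(tl), length(lags))
    for (i in seq_along(tl)) {
      tr <- tl[[i]]
      rel <- tr$frame - tr$frame[1]
      hit <- match(lags, rel)
      ok <- !is.na(hit)
      S[i, ok] <- (tr$x_um[hit[ok]] - tr$x_um[1])^2 +
        (tr$y_um[hit[ok]] - tr$y_um[1])^2
      N[i, ok] <- 1L
    }
    ts_sums <- list(S = S, N = N)
  }
  n_pairs <- colSums(ts_sums$N)
  keep <- n_pairs > 0
  curve <- data.frame(lag = lags[keep],
                      lag_min = lags[keep] * dt,
                      msd_um2 = colSums(ts_sums$S)[keep] / n_pairs[keep],
                      n_pairs = n_pairs[keep])
  structure(curve, class = c("msd_curve", "data.frame"),
            scheme = scheme, dt_min = dt,
            S = ts_sums$S[, keep, drop = FALSE],
            N = ts_sums$N[, keep, drop = FALSE],
            n_tracks = length(tl),
            excluded_tracks = sum(!eligible))
}

#' Fit the MSD power-law exponent
#'
#' Least-squares slope of `log MSD` vs `log lag` over the first quarter of
#' the available lags (at least 5), with a bootstrap-over-tracks
#' confidence interval. Exponent 1 is a random walk, 2 ballistic motion;
#' the ensemble is called superdiffusive when the CI lower bound exceeds
#' 1.
#'
#' @param curve an [msd()] result.
#' @param fit_frac fraction of available lags used for the fit.
#' @param min_lags minimum number of fitted lags.
#' @param min_pairs minimum pair count per fitted lag.
#' @param n_boot bootstrap replicates over tracks (default 200).
#' @param conf CI level (default 0.95).
#' @return an object of class `msd_fit`: `exponent`, `prefactor`
#'   (um^2/min^exponent), `r2`, `ci` (length-2), `fit_lags`,
#'   `superdiffusive`.
#' @export
fit_msd_exponent <- function(curve, fit_frac = 0.25, min_lags = 5L,
                             min_pairs = 20L, n_boot = 200L, conf = 0.95) {
  if (!inherits(curve, "msd_curve"))
    ds_stop("curve must be an msd_curve", "invalid_spec")
  n_fit <- max(min_lags, floor(nrow(curve) * fit_frac))
  if (nrow(curve) < n_fit)
    ds_stop(sprintf("need >= %d lags, have %d", n_fit, nrow(curve)),
            "fit_error")
  sel <- seq_len(n_fit)
  if (any(curve$n_pairs[sel] < min_pairs))
    ds_stop(sprintf("fewer than %d pairs at some fitted lag", min_pairs),
            "fit_error")
  if (any(curve$msd_um2[sel] <= 0))
    ds_stop("non-positive MSD in fit range: insufficient displacement",
            "fit_error")
  lx <- log(curve$lag_min[sel]); ly <- log(curve$msd_um2[sel])
  fit <- stats::lm(ly ~ lx)
  expo <- unname(coef(fit)[2])
  # summary.lm warns on numerically perfect fits (exact power laws)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  # bootstrap over tracks using the cached per-track sums
  S <- attr(curve, "S"); N <- attr(curve, "N")
  nt <- nrow(S)
  ci <- c(NA_real_, NA_real_)
  if (nt >= 2 && n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nt, nt, replace = TRUE)
      m <- colSums(S[idx, sel, drop = FALSE]) /
        pmax(colSums(N[idx, sel, drop = FALSE]), 1L)
      if (any(m <= 0)) return(NA_real_)
      unname(coef(stats::lm(log(m) ~ lx))[2])
    }, numeric(1))
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 10)
      ci <- unname(stats::quantile(boots, c((1 - conf) / 2,
                                            1 - (1 - conf) / 2)))
  }
  structure(list(exponent = expo,
                 prefactor = exp(unname(coef(fit)[1])),
                 r2 = r2, ci = ci, conf = conf, fit_lags = curve$lag[sel],
                 superdiffusive = is.finite(ci[1]) && ci[1] > 1),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> exponent %.3f (%.0f%% CI %.3f-%.3f), r2 = %.4f%s\n",
              x$exponent, 100 * x$conf, x$ci[1], x$ci[2], x$r2,
              if (isTRUE(x$superdiffusive)) ", superdiffusive" else ""))
  invisible(x)
}

#' Final displacement vectors and their vector sum
#'
#' Final-minus-initial displacement of every track, centered at the
#' origin (the compass-plot representation), with angles measured relative
#' to the chamber-opening direction (angle 0 = toward the opening /
#' nutrients; default opening direction is -x in image coordinates).
#'
#' @param tracks a [track_set].
#' @param opening_direction unit-normalized 2-vector pointing toward the
#'   chamber opening.
#' @return list with `vectors` (data.frame `track_id`, `dx_um`, `dy_um`,
#'   `magnitude_um`, `angle_rad`) and `vector_sum` (length-2).
#' @export
displacement_vectors <- function(tracks, opening_direction = c(-1, 0)) {
  u <- opening_direction / sqrt(sum(opening_direction^2))
  tl <- track_list(tracks)
  v <- t(vapply(tl, function(tr) {
    n <- nrow(tr)
    c(tr$x_um[n] - tr$x_um[1], tr$y_um[n] - tr$y_um[1])
  }, numeric(2)))
  # angle of each vector relative to the opening direction
  ang <- atan2(v[, 1] * u[2] - v[, 2] * u[1], v[, 1] * u[1] + v[, 2] * u[2])
  list(vectors = data.frame(track_id = names(tl),
                            dx_um = v[, 1], dy_um = v[, 2],
                            magnitude_um = sqrt(rowSums(v^2)),
                            angle_rad = ang, row.names = NULL),
       vector_sum = colSums(v))
}

#' Rayleigh (and Moore) test for directional bias
#'
#' Tests whether a set of angles is uniformly distributed on the circle.
#' The Rayleigh statistic is `Z = n * Rbar^2` with `Rbar` the mean
#' resultant length; the p-value uses the standard small-sample series
#' correction `exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 -
#' 9Z^4)/(288n^2))`. When displacement magnitudes are supplied, Moore's
#' rank-weighted variant is also computed (`R* = sqrt(X^2 + Y^2) /
#' n^{3/2}` with rank weights), with a Monte Carlo p-value.
#'
#' @param angles angles in radians (>= 5).
#' @param weights optional magnitudes for Moore's variant.
#' @param n_mc Monte Carlo replicates for Moore's p-value.
#' @return list with `rayleigh` (`statistic`, `r_bar`, `p_value`) and,
#'   when weights are given, `moore` (`statistic`, `p_value`).
#' @export
directional_test <- function(angles, weights = NULL, n_mc = 2000L) {
  n <- length(angles)
  if (n < 5) ds_stop("need at least 5 angles", "insufficient_data")
  C <- sum(cos(angles)); S <- sum(sin(angles))
  r_bar <- sqrt(C^2 + S^2) / n
  Z <- n * r_bar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) /
                    (288 * n^2))
  p <- min(max(p, 0), 1)
  out <- list(rayleigh = list(statistic = Z, r_bar = r_bar, p_value = p))
  if (!is.null(weights)) {
    if (length(weights) != n)
      ds_stop("weights length must match angles", "insufficient_data")
    rk <- rank(weights, ties.method = "average")
    Rstar <- moore_stat(angles, rk)
    null <- vapply(seq_len(n_mc), function(b)
      moore_stat(runif(n, 0, 2 * pi), rk), numeric(1))
    out$moore <- list(statistic = Rstar,
                      p_value = (1 + sum(null >= Rstar)) / (n_mc + 1))
  }
  out
}

moore_stat <- function(angles, ranks) {
  n <- length(angles)
  sqrt(sum(ranks * cos(angles))^2 + sum(ranks * sin(angles))^2) / n^1.5
}
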