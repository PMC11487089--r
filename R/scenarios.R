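#' Run a named analysis scenario
#'
#' Orchestrates the generators and analysis modules end to end and writes a
#' reproducible report bundle (CSV tables, a JSON summary, optional PNG
#' figures, and a manifest with the full config, package version and seed).
#' Built-in scenarios:
#'
#' * `fig2_invasiveness` — synthetic smooth-to-ruffled spheroid masks along
#'   the chamber axis; invasiveness index per spheroid and its linear fit
#'   against distance.
#' * `fig3_tracking` — two track ensembles (persistent "ischemic" vs
#'   brownian "well-nurtured"); speeds, persistence, runner statistics, MSD
#'   exponents, directional test.
#' * `fig4_cpm` — the four lattice-model conditions; metric time series and
#'   per-type MSD exponents.
#' * `fig2hi_ph` — ratiometric gradient image with and without consumer
#'   cells; estimated pH profiles.
#' * `fig7_taxol` — exponential drug-intensity decay; estimated
#'   concentration profile.
#'
#' The global seed fans out to one child seed per module via
#' [child_seed()], so module outputs are independent streams; the same
#' config and seed reproduce every artifact byte-identically.
#'
#' @param config either a scenario name (string) or a list with at least
#'   `scenario`; optional members: `seed` (default 1), `out_dir` (default
#'   `tempfile()`), `params` (scenario-specific overrides), `make_plots`.
#' @return list with `out_dir`, `summary` (scenario-specific), and
#'   `files` (paths written), invisibly also saved in the manifest.
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- list(scenario = config)
  if (is.null(config$scenario))
    ds_stop("config is missing required key 'scenario'", "config_error")
  scen <- config$scenario
  known <- c("fig2_invasiveness", "fig3_tracking", "fig4_cpm",
             "fig2hi_ph", "fig7_taxol")
  if (!scen %in% known)
    ds_stop(sprintf("unknown scenario '%s' (config key 'scenario')", scen),
            "config_error")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) tempfile("scenario_") else
    config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- if (is.null(config$params)) list() else config$params
  make_plots <- isTRUE(config$make_plots)

  runner <- switch(scen,
    fig2_invasiveness = scenario_invasiveness,
    fig3_tracking = scenario_tracking,
    fig4_cpm = scenario_cpm,
    fig2hi_ph = scenario_ph,
    fig7_taxol = scenario_taxol)
  res <- runner(seed, out_dir, params, make_plots)

  manifest <- list(scenario = scen, seed = seed,
                   package_version = as.character(packageVersion("dispersim")),
                   params = params, files = res$files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$out_dir <- out_dir
  invisible(res)
}

scenario_invasiveness <- function(seed, out_dir, params, make_plots) {
  dists <- params$distance_mm %||% seq(1, 11, by = 2)
  # ruffle amplitude grows with distance: distal spheroids are protrusive
  amps <- params$amplitudes %||% (0.35 * dists / max(dists))
  rows <- lapply(seq_along(dists), function(i) {
    spec <- shape_spec(radius_px = 80,
                       ruffle_amplitude = amps[i],
                       ruffle_modes = if (amps[i] > 0) c(7L) else integer(),
                       seed = child_seed(seed, i))
    data.frame(spheroid_id = sprintf("S%02d", i),
               distance_mm = dists[i],
               condition = "consumers",
               metric = "invasiveness_index",
               value = invasiveness_index(make_spheroid_mask(spec)))
  })
  tab <- do.call(rbind, rows)
  fit <- gradient_fit(tab$distance_mm, tab$value)
  f_csv <- file.path(out_dir, "invasiveness.csv")
  write.csv(tab, f_csv, row.names = FALSE)
  f_json <- file.path(out_dir, "invasiveness_fit.json")
  jsonlite::write_json(list(slope = fit$slope, intercept = fit$intercept,
                            r = fit$r, p_value = fit$p_value),
                       f_json, auto_unbox = TRUE, digits = NA)
  files <- c(f_csv, f_json)
  if (make_plots)
    files <- c(files, plot_xy(out_dir, "invasiveness.png",
                              tab$distance_mm, tab$value,
                              "distance to opening (mm)",
                              "invasiveness index"))
  list(summary = list(table = tab, fit = fit), files = files)
}

scenario_tracking <- function(seed, out_dir, params, make_plots) {
  n_tracks <- params$n_tracks %||% 150L
  n_steps <- params$n_steps %||% 96L
  conds <- list(
    well_nurtured = walk_spec("brownian", n_tracks, n_steps,
                              step_scale_um = 2,
                              seed = child_seed(seed, 1)),
    ischemic = walk_spec("persistent", n_tracks, n_steps,
                         step_scale_um = 2, persistence_time_min = 120,
                         seed = child_seed(seed, 2)))
  files <- character()
  summ <- list()
  per_track_all <- NULL
  for (nm in names(conds)) {
    ts <- make_tracks(conds[[nm]])
    f_tracks <- file.path(out_dir, paste0("tracks_", nm, ".csv"))
    write_tracks(ts, f_tracks)
    tl <- track_list(ts)
    per <- data.frame(
      condition = nm,
      track_id = names(tl),
      mean_speed_um_min = vapply(tl, function(t)
        mean(instantaneous_speeds(t)), numeric(1)),
      net_um = vapply(tl, net_displacement, numeric(1)),
      path_um = vapply(tl, path_length, numeric(1)),
      persistence = vapply(tl, function(t) as.numeric(persistence(t)),
                           numeric(1)),
      row.names = NULL)
    per_track_all <- rbind(per_track_all, per)
    runners <- classify_runners(ts)
    curve <- msd(ts)
    f_msd <- file.path(out_dir, paste0("msd_", nm, ".csv"))
    write.csv(data.frame(lag_min = curve$lag_min, msd_um2 = curve$msd_um2,
                         n_pairs = curve$n_pairs),
              f_msd, row.names = FALSE)
    fit <- fit_msd_exponent(curve)
    dv <- displacement_vectors(ts)
    dt_res <- directional_test(dv$vectors$angle_rad,
                               weights = dv$vectors$magnitude_um)
    summ[[nm]] <- list(exponent = fit$exponent, ci = fit$ci,
                       superdiffusive = fit$superdiffusive,
                       runner_count = runners$count,
                       runner_fraction = runners$fraction,
                       rayleigh_p = dt_res$rayleigh$p_value,
                       moore_p = dt_res$moore$p_value)
    files <- c(files, f_tracks, f_msd)
  }
  f_per <- file.path(out_dir, "per_track_metrics.csv")
  write.csv(per_track_all, f_per, row.names = FALSE)
  f_json <- file.path(out_dir, "tracking_summary.json")
  jsonlite::write_json(summ, f_json, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_per, f_json)
  list(summary = summ, files = files)
}

scenario_cpm <- function(seed, out_dir, params, make_plots) {
  scale <- params$scale %||% "desk"
  conds <- c("baseline", "low_adhesion", "invasion", "combined")
  files <- character()
  summ <- list()
  for (nm in conds) {
    res <- run_cpm(condition_params(nm, scale = scale,
                                    seed = child_seed(seed,
                                                      match(nm, conds))))
    f_m <- file.path(out_dir, paste0("cpm_metrics_", nm, ".csv"))
    write.csv(res$metrics, f_m, row.names = FALSE)
    f_t <- file.path(out_dir, paste0("cpm_tracks_", nm, ".csv"))
    write_tracks(res$tracks, f_t)
    cs <- cpm_summary(res)
    fit1 <- simulated_msd(res, "C1")
    summ[[nm]] <- list(
      invasion_C1 = cs$invasion_C1,
      invasion_C2 = cs$invasion_C2,
      mixing = cs$mixing,
      msd_exponent_C1 = if (is.null(fit1$rejected)) fit1$exponent else NA,
      msd_ci_C1 = if (is.null(fit1$rejected)) fit1$ci else c(NA, NA))
    files <- c(files, f_m, f_t)
  }
  f_json <- file.path(out_dir, "cpm_summary.json")
  jsonlite::write_json(summ, f_json, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_json)
  list(summary = summ, files = files)
}

scenario_ph <- function(seed, out_dir, params, make_plots) {
  axis_mm <- params$axis_length_mm %||% 12
  # calibration: ratio rises as pH falls (phenol red turns yellow)
  curve <- calibrate_ph(anchor_ratios = c(0.8, 1.0, 1.2, 1.4, 1.6),
                        anchor_ph = c(7.8, 7.4, 7.0, 6.6, 6.2))
  d <- seq(0, axis_mm, by = 0.25)
  profiles <- list(
    consumers = gradient_profile(d, 1.0 + 0.04 * d, "ratio"),
    no_consumers = gradient_profile(d, rep(1.0, length(d)), "ratio"))
  files <- character(); summ <- list()
  for (nm in names(profiles)) {
    img <- make_gradient_image(profiles[[nm]], axis_length_mm = axis_mm,
                               noise_sd = params$noise_sd %||% 0.01,
                               seed = child_seed(seed, match(nm,
                                                 names(profiles))))
    prof <- estimate_ph_profile(img, curve)
    f <- file.path(out_dir, paste0("ph_profile_", nm, ".csv"))
    write_profile(prof, f)
    fit <- gradient_fit(prof$distance_mm, prof$value)
    summ[[nm]] <- list(slope_ph_per_mm = fit$slope, r = fit$r,
                       p_value = fit$p_value)
    files <- c(files, f)
  }
  f_json <- file.path(out_dir, "ph_summary.json")
  jsonlite::write_json(summ, f_json, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_json)
  list(summary = summ, files = files)
}

scenario_taxol <- function(seed, out_dir, params, make_plots) {
  c0 <- params$c0_nM %||% 150
  ls_mm <- params$length_scale_mm %||% 8.3
  intensity <- make_decay_profile(c0 = 1, length_scale_mm = ls_mm,
                                  axis_length_mm = params$axis_length_mm
                                  %||% 12)
  conc <- estimate_drug_concentration(intensity, c0 = c0)
  f <- file.path(out_dir, "taxol_concentration.csv")
  write_profile(conc, f)
  at <- function(d) conc$value[which.min(abs(conc$distance_mm - d))]
  summ <- list(c0_nM = c0, nM_at_10mm = at(10), nM_at_12mm = at(12))
  f_json <- file.path(out_dir, "taxol_summary.json")
  jsonlite::write_json(summ, f_json, auto_unbox = TRUE, digits = NA)
  list(summary = summ, files = c(f, f_json))
}

plot_xy <- function(out_dir, name, x, y, xlab, ylab) {
  path <- file.path(out_dir, name)
  grDevices::png(path, width = 600, height = 450)
  on.exit(grDevices::dev.off())
  graphics::plot(x, y, pch = 19, xlab = xlab, ylab = ylab)
  graphics::abline(stats::lm(y ~ x), lty = 2)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
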