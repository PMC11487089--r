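# type codes used throughout the lattice model
CPM_TYPES <- c(M = 0L, C1 = 1L, C2 = 2L)

#' Cellular Potts model parameters
#'
#' Parameter bundle for the two-cell-type spheroid simulation: a core of
#' ischemic cells (C1) surrounded by well-perfused cortical cells (C2),
#' embedded in an ECM/medium compartment (M). The contact-energy table `J`
#' encodes differential adhesion — high J means an unstable, low-affinity
#' contact — and the volume constraint `lambda_volume * (v - V_target)^2`
#' keeps cells near their target size. Dynamics are Metropolis-accepted
#' spin-copy attempts at temperature `temperature`; one Monte Carlo step is
#' accounted as one copy attempt by default (`mcs_accounting = "sweeps"`
#' multiplies by the lattice size instead).
#'
#' @param grid lattice size `c(width, height)` in sites.
#' @param n_cells number of cells.
#' @param core_fraction fraction of cells typed C1 (innermost at init).
#' @param J symmetric 3x3 contact-energy matrix with dimnames
#'   `c("M", "C1", "C2")`; `J["M","M"]` must be 0.
#' @param lambda_volume volume-constraint weight (>= 0).
#' @param V_target target cell volume in sites.
#' @param temperature Metropolis temperature (> 0 for stochastic dynamics).
#' @param n_mcs total Monte Carlo steps.
#' @param record_every attempts between snapshots.
#' @param seed integer RNG seed.
#' @param neighborhood_order 1 = 4-neighbor (von Neumann), 2 = 8-neighbor
#'   (Moore, default; less lattice anisotropy).
#' @param connectivity enforce local cell connectivity: a site may not be
#'   removed from a cell when its same-cell neighbors do not form one
#'   contiguous arc of the 8-ring (prevents cell fragmentation).
#' @param mcs_accounting `"attempts"` (default) or `"sweeps"`.
#' @return an object of class `cpm_params`.
#' @export
cpm_params <- function(grid = c(200L, 200L), n_cells = 100L,
                       core_fraction = 0.3, J = NULL, lambda_volume = 1,
                       V_target = 25, temperature = 8, n_mcs = 1.28e8,
                       record_every = 1.28e6, seed = 1L,
                       neighborhood_order = 2L, connectivity = FALSE,
                       mcs_accounting = c("attempts", "sweeps")) {
  mcs_accounting <- match.arg(mcs_accounting)
  if (is.null(J)) J <- j_table(8, 8, 8, 16, 16)
  if (!is.matrix(J) || !identical(dim(J), c(3L, 3L)) ||
      !identical(rownames(J), c("M", "C1", "C2")))
    ds_stop("J must be a 3x3 matrix with dimnames M, C1, C2",
            "config_error")
  if (any(J != t(J))) ds_stop("J must be symmetric", "config_error")
  if (any(!is.finite(J))) ds_stop("J must be finite", "config_error")
  if (lambda_volume < 0) ds_stop("lambda_volume must be >= 0",
                                 "config_error")
  if (core_fraction <= 0 || core_fraction >= 1)
    ds_stop("core_fraction must be in (0, 1)", "config_error")
  if (!neighborhood_order %in% c(1L, 2L))
    ds_stop("neighborhood_order must be 1 or 2", "config_error")
  structure(list(grid = as.integer(grid), n_cells = as.integer(n_cells),
                 core_fraction = core_fraction, J = J,
                 lambda_volume = lambda_volume, V_target = V_target,
                 temperature = temperature, n_mcs = n_mcs,
                 record_every = record_every, seed = as.integer(seed),
                 neighborhood_order = as.integer(neighborhood_order),
                 connectivity = isTRUE(connectivity),
                 mcs_accounting = mcs_accounting),
            class = "cpm_params")
}

# build the symmetric contact table from the five free energies
j_table <- function(j11, j12, j22, j1m, j2m) {
  J <- matrix(0, 3, 3, dimnames = list(c("M", "C1", "C2"),
                                       c("M", "C1", "C2")))
  J["C1", "C1"] <- j11
  J["C1", "C2"] <- J["C2", "C1"] <- j12
  J["C2", "C2"] <- j22
  J["M", "C1"] <- J["C1", "M"] <- j1m
  J["M", "C2"] <- J["C2", "M"] <- j2m
  J
}

#' Condition presets for the dispersal simulation
#'
#' The four simulated conditions: `baseline` (symmetric cell adhesion,
#' equal ECM affinity — cells neither mix nor invade), `low_adhesion`
#' (core-core contacts destabilized, `J_C1C1 > J_C1C2 > J_C2C2`, modeling
#' the E-cadherin loss of ischemic cells — core cells mix into the cortex
#' but stay in the tissue), `invasion` (core cells gain ECM affinity,
#' `J_C1M < J_C2M`), and `combined` (both). Absolute energies are package
#' defaults chosen to satisfy those orderings with mid-range contrast; the
#' core qualitative contrasts (combined disperses more than baseline,
#' low_adhesion mixes more than baseline) are robust to a ±25% scaling of
#' the energy tables.
#'
#' @param name one of `"baseline"`, `"low_adhesion"`, `"invasion"`,
#'   `"combined"`.
#' @param scale `"full"` (200x200 lattice, 100 cells, 1.28e8 attempts) or
#'   `"desk"` (100x100, 25 cells, 2e6 attempts; for routine runs).
#' @param seed integer seed.
#' @param j_scale multiplier applied to all cell-related J entries (used
#'   for robustness sweeps).
#' @return a [cpm_params].
#' @export
condition_params <- function(name = c("baseline", "low_adhesion",
                                      "invasion", "combined"),
                             scale = c("full", "desk"), seed = 1L,
                             j_scale = 1) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% c("baseline", "low_adhesion", "invasion", "combined")))
    ds_stop(sprintf("unknown condition '%s'", paste(name, collapse = "/")),
            "config_error")
  scale <- match.arg(scale)
  J <- switch(name,
    baseline     = j_table(8, 8, 8, 16, 16),
    low_adhesion = j_table(16, 6, 4, 16, 16),
    invasion     = j_table(8, 8, 8, 10, 16),
    combined     = j_table(16, 6, 4, 6, 16)) * j_scale
  p <- if (scale == "full") {
    cpm_params(grid = c(200L, 200L), n_cells = 100L, J = J,
               n_mcs = 1.28e8, record_every = 1.28e6, seed = seed)
  } else {
    cpm_params(grid = c(100L, 100L), n_cells = 25L, J = J,
               n_mcs = 2e6, record_every = 2e4, seed = seed)
  }
  p$condition <- name
  # enforce the printed hierarchies for the perturbed table too
  if (name %in% c("low_adhesion", "combined")) {
    if (!(p$J["C1", "C1"] > p$J["C1", "C2"] &&
          p$J["C1", "C2"] > p$J["C2", "C2"]))
      ds_stop("adhesion hierarchy J_C1C1 > J_C1C2 > J_C2C2 violated",
              "config_error")
  }
  if (name %in% c("invasion", "combined")) {
    if (!(p$J["C1", "M"] < p$J["C2", "M"]))
      ds_stop("ECM-affinity hierarchy J_C1M < J_C2M violated",
              "config_error")
  }
  p
}

#' Initialize the lattice state
#'
#' Seeds a circular cluster centered on the grid: cell seed points are laid
#' out on a sunflower (phyllotaxis) spiral filling a disk of area
#' `n_cells * V_target`, every lattice site inside the disk is assigned to
#' its nearest seed, and the `core_fraction` of cells with the innermost
#' centroids are typed C1 (ischemic core), the rest C2 (cortex). All
#' surrounding sites are ECM/medium (spin 0).
#'
#' @param params a [cpm_params].
#' @return an object of class `cpm_state` with fields `spins` (integer
#'   matrix), `cell_types` (per-cell 1 = C1, 2 = C2), `volumes`,
#'   `attempts`, and `initial_in_cluster` (logical matrix recording the
#'   initial cluster footprint).
#' @export
init_state <- function(params) {
  W <- params$grid[1]; H <- params$grid[2]
  n <- params$n_cells
  rad <- sqrt(n * params$V_target / pi)
  if (2 * rad > min(W, H) - 8)
    ds_stop("cells do not fit the grid with margin", "config_error")
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  sr <- rad * sqrt((i - 0.5) / n)
  sx <- cx + sr * cos(i * golden)
  sy <- cy + sr * sin(i * golden)
  # assign every in-disk site to the nearest seed; a few Lloyd iterations
  # (seeds -> cell centroids -> reassign) even out the cell volumes
  gx <- matrix(seq_len(W), H, W, byrow = TRUE)
  gy <- matrix(seq_len(H), H, W)
  in_disk <- (gx - cx)^2 + (gy - cy)^2 <= rad^2
  px <- gx[in_disk]; py <- gy[in_disk]
  # Lloyd steps with per-cell power weights adapted toward equal volumes
  # (a capacity-balanced power diagram), so seeded volumes sit close to
  # V_target
  w <- numeric(n)
  best <- NULL; best_dev <- Inf
  for (it in 1:120) {
    d2 <- outer(px, sx, function(a, b) (a - b)^2) +
      outer(py, sy, function(a, b) (a - b)^2)
    owner <- max.col(-(sweep(d2, 2, w)), ties.method = "first")
    vols <- tabulate(owner, n)
    if (it <= 6) {
      sx2 <- as.numeric(tapply(px, factor(owner, levels = i), mean))
      sy2 <- as.numeric(tapply(py, factor(owner, levels = i), mean))
      sx <- ifelse(is.na(sx2), sx, sx2)
      sy <- ifelse(is.na(sy2), sy, sy2)
    }
    dev <- max(abs(vols - params$V_target))
    if (it > 6 && dev < best_dev) { best <- owner; best_dev <- dev }
    w <- w + 0.5 / sqrt(it) * (params$V_target - vols)
    w <- w - mean(w)
  }
  owner <- best
  spins <- matrix(0L, H, W)
  spins[in_disk] <- owner
  vols <- tabulate(owner, n)
  if (any(vols == 0L))
    ds_stop("degenerate seeding: empty cell", "config_error")
  # type by centroid radius so every core centroid is inner to every
  # cortical centroid
  crad <- sqrt((sx - cx)^2 + (sy - cy)^2)
  n_core <- max(1L, round(params$core_fraction * n))
  types <- rep(2L, n)
  types[order(crad)[seq_len(n_core)]] <- 1L
  structure(list(spins = spins, cell_types = types,
                 volumes = as.numeric(vols), attempts = 0,
                 initial_in_cluster = in_disk),
            class = "cpm_state")
}

#' Total energy of a lattice state
#'
#' Graner–Glazier Hamiltonian: the contact energy `J(tau_i, tau_j)` summed
#' over all neighboring site pairs with different spins, plus the volume
#' term `lambda * (v - V_target)^2` summed over cells.
#'
#' @param state a [cpm_state].
#' @param params the matching [cpm_params].
#' @return scalar energy (dimensionless).
#' @export
hamiltonian <- function(state, params) {
  spins <- state$spins
  type_of <- c(0L, state$cell_types)[spins + 1L]
  dim(type_of) <- dim(spins)
  H <- nrow(spins); W <- ncol(spins)
  offs <- neighbor_offsets(params$neighborhood_order)
  # count each unordered pair once: only "forward" offsets
  fwd <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0), ,
              drop = FALSE]
  e_contact <- 0
  for (k in seq_len(nrow(fwd))) {
    dr <- fwd[k, 1]; dc <- fwd[k, 2]
    r1 <- seq_len(H - abs(dr)) + max(0, -dr)
    c1 <- seq_len(W - abs(dc)) + max(0, -dc)
    r2 <- r1 + dr; c2 <- c1 + dc
    a <- spins[r1, c1, drop = FALSE]; b <- spins[r2, c2, drop = FALSE]
    ta <- type_of[r1, c1, drop = FALSE]; tb <- type_of[r2, c2, drop = FALSE]
    diffm <- a != b
    if (any(diffm))
      e_contact <- e_contact +
        sum(params$J[cbind(ta[diffm] + 1L, tb[diffm] + 1L)])
  }
  vols <- tabulate(spins[spins > 0L], params$n_cells)
  e_contact + params$lambda_volume * sum((vols - params$V_target)^2)
}

neighbor_offsets <- function(order) {
  if (order == 1L) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
}

#' Perform a single copy attempt
#'
#' One step of the kinetic kernel: pick a random lattice site and a random
#' neighbor, propose copying the neighbor's spin onto the site, and accept
#' with the Metropolis probability `min(1, exp(-dE / T))` computed from the
#' local energy change. Exposed mainly for auditing; [run_cpm()] performs
#' attempts in bulk in compiled code.
#'
#' @param state a [cpm_state].
#' @param params the matching [cpm_params].
#' @return list with the updated `state`, `accepted` flag, and `delta_e`
#'   (NA for no-op proposals).
#' @export
attempt_copy <- function(state, params) {
  res <- cpm_audit_cpp(state$spins, state$cell_types, unname(params$J),
                       params$lambda_volume, params$V_target,
                       params$temperature, 1L,
                       params$neighborhood_order, params$connectivity,
                       FALSE)
  state$spins <- res$spins
  state$volumes <- res$volumes
  state$attempts <- state$attempts + 1
  list(state = state, accepted = res$accepted[1] == 1L,
       delta_e = res$delta_e[1])
}

#' Run the cellular Potts simulation
#'
#' Executes `n_mcs` copy attempts from [init_state()], recording the spin
#' field every `record_every` attempts. From the snapshots it derives
#' per-cell centroid tracks (one sample per snapshot, time measured in
#' recorded frames) and a metric time series: total energy,
#' [mixing_index()], and per-type [ecm_invasion_fraction()]. Fully
#' reproducible for a given seed.
#'
#' @param params a [cpm_params].
#' @param state optional starting [cpm_state] (e.g. the final state of a
#'   previous run); defaults to a fresh [init_state()].
#' @return an object of class `cpm_result`: `params`, `snapshots` (list of
#'   spin matrices), `snapshot_attempts`, `state` (final), `tracks` (a
#'   [track_set] of cell centroids with a `cell_type` attribute),
#'   `metrics` (data.frame), `initial_in_cluster`, `accepted`.
#' @export
run_cpm <- function(params, state = NULL) {
  if (!inherits(params, "cpm_params"))
    ds_stop("params must be cpm_params", "config_error")
  if (is.null(state)) state <- init_state(params)
  n_att <- params$n_mcs
  if (params$mcs_accounting == "sweeps")
    n_att <- n_att * prod(params$grid)
  res <- with_seed(params$seed,
    cpm_evolve_cpp(state$spins, state$cell_types, unname(params$J),
                   params$lambda_volume, params$V_target,
                   params$temperature, n_att, params$record_every,
                   params$neighborhood_order, params$connectivity))
  final <- state
  final$spins <- res$spins
  final$volumes <- res$volumes
  final$attempts <- n_att
  if (any(border_touch(res$spins)))
    ds_warn("a cell touches the lattice border: grid too small for these dynamics",
            "cpm_border_warning")
  snaps <- res$snapshots
  tracks <- centroid_tracks(snaps, res$snapshot_attempts,
                            state$cell_types)
  metrics <- data.frame(
    attempt = res$snapshot_attempts,
    energy = vapply(snaps, function(s) {
      st <- state; st$spins <- s
      hamiltonian(st, params)
    }, numeric(1)),
    mixing_index = vapply(snaps, function(s) {
      st <- state; st$spins <- s
      mixing_index(st, params)
    }, numeric(1)))
  inv <- t(vapply(snaps, function(s) {
    st <- state; st$spins <- s
    ecm_invasion_fraction(st, state$initial_in_cluster)
  }, numeric(2)))
  metrics$invasion_C1 <- inv[, 1]
  metrics$invasion_C2 <- inv[, 2]
  structure(list(params = params, snapshots = snaps,
                 snapshot_attempts = res$snapshot_attempts,
                 state = final, tracks = tracks, metrics = metrics,
                 initial_in_cluster = state$initial_in_cluster,
                 accepted = res$accepted),
            class = "cpm_result")
}

border_touch <- function(spins) {
  c(spins[1, ], spins[nrow(spins), ], spins[, 1], spins[, ncol(spins)]) > 0L
}

# centroid track_set from a snapshot list; cells with zero volume in a
# snapshot contribute no sample there
centroid_tracks <- function(snaps, attempts, cell_types) {
  rows <- lapply(seq_along(snaps), function(si) {
    s <- snaps[[si]]
    idx <- which(s > 0L)
    if (!length(idx)) return(NULL)
    id <- s[idx]
    r <- (idx - 1L) %% nrow(s) + 1L
    cc <- (idx - 1L) %/% nrow(s) + 1L
    data.frame(track_id = as.integer(names(tapply(r, id, mean))),
               frame = si,
               t_min = si - 1,
               x_um = as.numeric(tapply(cc, id, mean)),
               y_um = as.numeric(tapply(r, id, mean)))
  })
  df <- do.call(rbind, rows)
  ts <- track_set(df, dt_min = 1)
  attr(ts, "cell_type") <- cell_types
  ts
}

#' Core/cortex mixing index
#'
#' Fraction of heterotypic (C1–C2) contacts among all cell–cell contacts,
#' normalized by its expectation under random assignment of the same type
#' counts to cells (`2 n1 n2 / (n (n-1))`). The perfectly sorted initial
#' layout scores well below 1, a random arrangement about 1, and
#' checkerboard-like maximal mixing above 1.
#'
#' @param state a [cpm_state].
#' @param params the matching [cpm_params] (for the neighborhood).
#' @return normalized mixing index; `NA` (flagged with a warning) when a
#'   type is absent.
#' @export
mixing_index <- function(state, params) {
  spins <- state$spins
  live <- sort(unique(spins[spins > 0L]))
  tys <- state$cell_types[live]
  n1 <- sum(tys == 1L); n2 <- sum(tys == 2L)
  if (n1 == 0L || n2 == 0L) {
    ds_warn("a cell type is absent; mixing index undefined",
            "cpm_metric_warning")
    return(NA_real_)
  }
  type_of <- c(0L, state$cell_types)[spins + 1L]
  dim(type_of) <- dim(spins)
  offs <- neighbor_offsets(params$neighborhood_order)
  fwd <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0), ,
              drop = FALSE]
  het <- 0; tot <- 0
  H <- nrow(spins); W <- ncol(spins)
  for (k in seq_len(nrow(fwd))) {
    dr <- fwd[k, 1]; dc <- fwd[k, 2]
    r1 <- seq_len(H - abs(dr)) + max(0, -dr)
    c1 <- seq_len(W - abs(dc)) + max(0, -dc)
    a <- spins[r1, c1, drop = FALSE]
    b <- spins[r1 + dr, c1 + dc, drop = FALSE]
    ta <- type_of[r1, c1, drop = FALSE]
    tb <- type_of[r1 + dr, c1 + dc, drop = FALSE]
    cc <- a > 0L & b > 0L & a != b
    tot <- tot + sum(cc)
    het <- het + sum(cc & ta != tb)
  }
  if (tot == 0) return(NA_real_)
  n <- n1 + n2
  (het / tot) / (2 * n1 * n2 / (n * (n - 1)))
}

#' Fraction of each cell type outside the initial cluster
#'
#' Measures ECM invasion: the fraction of each type's total volume lying
#' outside the initial cluster footprint dilated by 2 sites (the dilation
#' ignores mere boundary jitter).
#'
#' @param state a [cpm_state].
#' @param initial_in_cluster logical matrix recorded at init.
#' @param dilate dilation radius in sites (default 2, Moore).
#' @return named numeric `c(C1 = ..., C2 = ...)`.
#' @export
ecm_invasion_fraction <- function(state, initial_in_cluster, dilate = 2L) {
  region <- initial_in_cluster
  for (i in seq_len(dilate)) region <- dilate_moore(region)
  type_of <- c(0L, state$cell_types)[state$spins + 1L]
  dim(type_of) <- dim(state$spins)
  out <- vapply(1:2, function(ty) {
    tot <- sum(type_of == ty)
    if (tot == 0) return(NA_real_)
    sum(type_of == ty & !region) / tot
  }, numeric(1))
  names(out) <- c("C1", "C2")
  out
}

dilate_moore <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  shifts <- neighbor_offsets(2L)
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts[k, 1]; dc <- shifts[k, 2]
    r1 <- seq_len(H - abs(dr)) + max(0, -dr)
    c1 <- seq_len(W - abs(dc)) + max(0, -dc)
    out[r1, c1] <- out[r1, c1] | m[r1 + dr, c1 + dc]
  }
  out
}

#' Summarize a simulation's dispersal metrics
#'
#' Collapses the metric time series of a run into per-run summaries that
#' are stable against single-snapshot noise: the ECM-invasion fraction is
#' averaged over the last quarter of snapshots (late-time state), the
#' mixing index over all post-initial snapshots (sensitive to the mixing
#' rate, which is what separates an actively mixing tissue from slow
#' neutral drift).
#'
#' @param result a [run_cpm()] result.
#' @return list with `invasion_C1`, `invasion_C2`, `mixing`.
#' @export
cpm_summary <- function(result) {
  m <- result$metrics[-1, , drop = FALSE]
  late <- m[m$attempt >= 0.75 * max(m$attempt), , drop = FALSE]
  list(invasion_C1 = mean(late$invasion_C1),
       invasion_C2 = mean(late$invasion_C2),
       mixing = mean(m$mixing_index))
}

#' MSD exponent of simulated cell tracks
#'
#' Pools the centroid tracks of one cell type from a simulation and fits
#' the MSD power-law exponent ([msd()] + [fit_msd_exponent()]). When the
#' dynamics are frozen (insufficient displacement for a log-log fit) the
#' fit is rejected and flagged rather than forced.
#'
#' @param result a [run_cpm()] result (>= 20 snapshots).
#' @param cell_type `"C1"` (core) or `"C2"` (cortical).
#' @param ... passed to [fit_msd_exponent()].
#' @return an `msd_fit`, or a list with `rejected = TRUE` and `reason`
#'   when the fit is impossible.
#' @export
simulated_msd <- function(result, cell_type = c("C1", "C2"), ...) {
  cell_type <- match.arg(cell_type)
  if (length(result$snapshots) < 20)
    ds_stop("need at least 20 snapshots", "input_error")
  ty <- CPM_TYPES[cell_type]
  ids <- which(attr(result$tracks, "cell_type") == ty)
  sub <- result$tracks[result$tracks$track_id %in% ids, ]
  sub <- track_set(as.data.frame(sub), dt_min = attr(result$tracks, "dt_min"))
  tryCatch(fit_msd_exponent(msd(sub), ...),
           fit_error = function(e)
             list(rejected = TRUE, reason = conditionMessage(e)))
}
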