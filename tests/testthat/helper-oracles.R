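# Independent oracles used across the suite. These are deliberately naive
# (enumeration / brute force) and never share code with the implementation.

# dense-polygon perimeter/area of the analytic star-convex boundary
# r(theta) = R * (1 + A * sum_k sin(k theta + phi_k))
oracle_shape_metrics <- function(radius, amplitude, modes, phases,
                                 n = 200000) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  r <- rep(radius, n)
  for (i in seq_along(modes))
    r <- r + radius * amplitude * sin(modes[i] * th + phases[i])
  x <- r * cos(th); y <- r * sin(th)
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  list(perimeter = per, area = area,
       invasiveness = per / (2 * sqrt(pi * area)))
}

# brute-force Delaunay: a triple is Delaunay iff no other point lies
# strictly inside its circumcircle (general position assumed)
oracle_delaunay <- function(x, y) {
  n <- length(x)
  out <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    inside <- (x - ux)^2 + (y - uy)^2 < r2 * (1 - 1e-12)
    inside[c(i, j, k)] <- FALSE
    if (!any(inside)) out <- rbind(out, sort(c(i, j, k)))
  }
  colnames(out) <- c("i", "j", "k")
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# all-pairs time-averaged MSD, quadratic in track length
oracle_msd <- function(tracks, max_lag) {
  tl <- split(as.data.frame(tracks), tracks$track_id)
  sums <- numeric(max_lag); counts <- integer(max_lag)
  for (tr in tl) {
    n <- nrow(tr)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      lag <- tr$frame[b] - tr$frame[a]
      if (lag >= 1 && lag <= max_lag) {
        d2 <- (tr$x_um[b] - tr$x_um[a])^2 + (tr$y_um[b] - tr$y_um[a])^2
        sums[lag] <- sums[lag] + d2
        counts[lag] <- counts[lag] + 1L
      }
    }
  }
  data.frame(lag = seq_len(max_lag), msd = sums / counts,
             n_pairs = counts)
}

# site-by-site enumeration of the lattice Hamiltonian (slow, explicit)
oracle_hamiltonian <- function(spins, cell_types, J, lambda, vtarget,
                               neighborhood = 2L) {
  H <- nrow(spins); W <- ncol(spins)
  offs <- if (neighborhood == 1L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
            c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  ty <- function(s) if (s == 0) 0L else cell_types[s]
  e <- 0
  for (r in 1:H) for (c in 1:W) for (o in offs) {
    r2 <- r + o[1]; c2 <- c + o[2]
    if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
    if (spins[r, c] != spins[r2, c2])
      e <- e + J[ty(spins[r, c]) + 1L, ty(spins[r2, c2]) + 1L] / 2
  }
  vols <- tabulate(spins[spins > 0], length(cell_types))
  e + lambda * sum((vols - vtarget)^2)
}

# closed-form MSD of the 2D persistent random walk (Fuerth): speed v,
# persistence time P
oracle_furth_msd <- function(tau, v, P) {
  2 * v^2 * P * (tau - P * (1 - exp(-tau / P)))
}

# random small track_set builder
random_tracks <- function(n_tracks, n_steps, dt = 15, seed = 1) {
  make_tracks(walk_spec("brownian", n_tracks, n_steps, dt_min = dt,
                        step_scale_um = 3, seed = seed))
}

# random lattice state for kinetic-kernel audits
random_state <- function(seed, n = 20L, n_cells = 3L) {
  set.seed(seed)
  spins <- matrix(sample(0:n_cells, n * n, replace = TRUE), n, n)
  types <- rep(c(1L, 2L), length.out = n_cells)
  structure(list(spins = spins, cell_types = types,
                 volumes = as.numeric(tabulate(spins[spins > 0], n_cells)),
                 attempts = 0,
                 initial_in_cluster = spins > 0),
            class = "cpm_state")
}

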