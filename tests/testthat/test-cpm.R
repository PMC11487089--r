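test_that("condition presets satisfy the printed energy hierarchies", {
  la <- condition_params("low_adhesion")
  expect_true(la$J["C1", "C1"] > la$J["C1", "C2"])
  expect_true(la$J["C1", "C2"] > la$J["C2", "C2"])
  expect_equal(la$J["C1", "M"], la$J["C2", "M"])

  inv <- condition_params("invasion")
  expect_lt(inv$J["C1", "M"], inv$J["C2", "M"])
  expect_equal(inv$J["C1", "C1"], inv$J["C2", "C2"])
  expect_equal(inv$J["C1", "C2"], inv$J["C1", "C1"])

  co <- condition_params("combined")
  expect_true(co$J["C1", "C1"] > co$J["C1", "C2"] &&
                co$J["C1", "C2"] > co$J["C2", "C2"])
  expect_lt(co$J["C1", "M"], co$J["C2", "M"])

  ba <- condition_params("baseline")
  expect_equal(length(unique(c(ba$J["C1", "C1"], ba$J["C1", "C2"],
                               ba$J["C2", "C2"]))), 1L)
  expect_equal(ba$J["C1", "M"], ba$J["C2", "M"])

  # full-scale preset mirrors the published run geometry
  full <- condition_params("baseline", scale = "full")
  expect_equal(full$grid, c(200L, 200L))
  expect_equal(full$n_cells, 100L)
  expect_equal(full$n_mcs, 1.28e8)

  expect_error(condition_params("sideways"), class = "config_error")
  # perturbations that break a hierarchy are rejected
  expect_error(cpm_params(J = matrix(1, 3, 3)), class = "config_error")
})

test_that("initial state seeds a typed core/cortex cluster", {
  p <- condition_params("baseline", "desk")
  st <- init_state(p)
  expect_equal(sum(st$cell_types == 1L), round(0.3 * 25))
  expect_equal(sum(st$volumes), sum(st$spins > 0))
  # volumes within +-20% of target at seeding
  expect_true(all(abs(st$volumes - p$V_target) <= 0.2 * p$V_target))
  # every core centroid is closer to the center than every cortical one
  cx <- (p$grid[1] + 1) / 2
  idx <- which(st$spins > 0)
  r <- (idx - 1) %% nrow(st$spins) + 1
  cc <- (idx - 1) %/% nrow(st$spins) + 1
  cenr <- tapply(r, st$spins[idx], mean)
  cenc <- tapply(cc, st$spins[idx], mean)
  rad <- sqrt((cenr - cx)^2 + (cenc - cx)^2)
  expect_lt(max(rad[st$cell_types == 1L]), min(rad[st$cell_types == 2L]))

  # overfull grids are rejected
  expect_error(init_state(cpm_params(grid = c(30L, 30L), n_cells = 100L)),
               class = "config_error")
})

test_that("hamiltonian matches site-by-site enumeration", {
  # single 4x4 square cell, 4-neighborhood: 16 boundary pairs
  spins <- matrix(0L, 12, 12)
  spins[5:8, 5:8] <- 1L
  st <- structure(list(spins = spins, cell_types = 1L, volumes = 16,
                       attempts = 0, initial_in_cluster = spins > 0),
                  class = "cpm_state")
  j <- 3.5; lam <- 2; vt <- 20
  p <- cpm_params(grid = c(12L, 12L), n_cells = 1L,
                  J = dispersim:::j_table(5, 5, 5, j, j),
                  lambda_volume = lam, V_target = vt,
                  neighborhood_order = 1L)
  expect_equal(hamiltonian(st, p), 16 * j + lam * (16 - vt)^2)

  # empty lattice has zero energy (no cells, no contacts)
  st0 <- st; st0$spins <- matrix(0L, 12, 12); st0$volumes <- 0
  p0 <- cpm_params(grid = c(12L, 12L), n_cells = 1L,
                   J = dispersim:::j_table(5, 5, 5, j, j),
                   lambda_volume = 0, V_target = 0)
  expect_equal(hamiltonian(st0, p0), 0)

  # random mixed states vs the explicit enumeration oracle, both
  # neighborhood orders
  for (seed in 1:6) {
    st <- random_state(seed)
    for (nb in c(1L, 2L)) {
      p <- cpm_params(grid = c(20L, 20L), n_cells = 3L,
                      J = dispersim:::j_table(7, 3, 2, 9, 11),
                      lambda_volume = 1.5, V_target = 30,
                      neighborhood_order = nb)
      expect_equal(hamiltonian(st, p),
                   oracle_hamiltonian(st$spins, st$cell_types, p$J,
                                      1.5, 30, nb))
    }
  }
})

test_that("local delta-E agrees with global recomputation on 500 moves", {
  st <- random_state(42)
  p <- cpm_params(grid = c(20L, 20L), n_cells = 3L,
                  J = dispersim:::j_table(7, 3, 2, 9, 11),
                  lambda_volume = 1.5, V_target = 30, temperature = 20)
  set.seed(7)
  audit <- dispersim:::cpm_audit_cpp(st$spins, st$cell_types, unname(p$J),
                                     p$lambda_volume, p$V_target,
                                     p$temperature, 500L, 2L, FALSE, TRUE)
  prev <- st
  h_prev <- hamiltonian(prev, p)
  checked <- 0L
  for (i in seq_len(500)) {
    cur <- prev
    cur$spins <- audit$snapshots[[i]]
    if (audit$accepted[i] == 1L) {
      h_cur <- hamiltonian(cur, p)
      expect_equal(h_cur - h_prev, audit$delta_e[i], tolerance = 1e-9)
      h_prev <- h_cur
      checked <- checked + 1L
    } else {
      # rejected moves must not alter the lattice
      expect_identical(cur$spins, prev$spins)
    }
    prev <- cur
  }
  expect_gt(checked, 100L)
})

test_that("single attempts behave at the temperature limits", {
  st <- random_state(3)
  # T -> 0: only downhill moves pass
  p0 <- cpm_params(grid = c(20L, 20L), n_cells = 3L,
                   J = dispersim:::j_table(7, 3, 2, 9, 11),
                   lambda_volume = 1.5, V_target = 30, temperature = 0)
  set.seed(11)
  for (i in 1:200) {
    out <- attempt_copy(st, p0)
    if (out$accepted) expect_lte(out$delta_e, 0)
    st <- out$state
  }
})

test_that("volume caches equal recounts and a lone cell keeps its volume", {
  p <- condition_params("combined", "desk", seed = 4L)
  p$n_mcs <- 1e5; p$record_every <- 1e4
  res <- run_cpm(p)
  for (i in seq_along(res$snapshots)) {
    s <- res$snapshots[[i]]
    expect_equal(sum(s > 0), sum(tabulate(s[s > 0], p$n_cells)))
  }
  expect_equal(res$state$volumes,
               as.numeric(tabulate(res$state$spins[res$state$spins > 0],
                                   p$n_cells)))

  # detailed-balance smoke test: a single cell fluctuates around V_target
  p1 <- cpm_params(grid = c(40L, 40L), n_cells = 1L, core_fraction = 0.5,
                   J = dispersim:::j_table(4, 4, 4, 6, 6),
                   lambda_volume = 1, V_target = 25, temperature = 6,
                   n_mcs = 4e5, record_every = 4e3, seed = 9L)
  res1 <- suppressWarnings(run_cpm(p1))
  vols <- vapply(res1$snapshots[-(1:20)], function(s) sum(s > 0),
                 numeric(1))
  expect_lt(abs(mean(vols) - 25), 3)
})

test_that("zero-temperature energy trajectories never increase", {
  p <- condition_params("baseline", "desk", seed = 2L)
  p$temperature <- 0; p$n_mcs <- 2e5; p$record_every <- 5e3
  res <- run_cpm(p)
  expect_true(all(diff(res$metrics$energy) <= 1e-9))
})

test_that("runs are seed-reproducible and zero-length runs are identity", {
  p <- condition_params("combined", "desk", seed = 8L)
  p$n_mcs <- 2e5; p$record_every <- 2e4
  r1 <- run_cpm(p); r2 <- run_cpm(p)
  expect_identical(r1$state$spins, r2$state$spins)
  expect_equal(r1$metrics, r2$metrics)
  p2 <- p; p2$seed <- 9L
  r3 <- run_cpm(p2)
  expect_false(identical(r1$state$spins, r3$state$spins))

  p0 <- p; p0$n_mcs <- 0
  r0 <- run_cpm(p0)
  expect_equal(length(r0$snapshots), 1L)
  expect_identical(r0$snapshots[[1]], init_state(p)$spins)
})

test_that("mixing index separates sorted, random, and checkerboard types", {
  # 6x6 grid of 4x4-site cells on a 24x24 lattice
  blocks <- matrix(0L, 24, 24)
  for (i in 0:5) for (j in 0:5)
    blocks[i * 4 + 1:4, j * 4 + 1:4] <- i * 6 + j + 1L
  mk <- function(types) structure(
    list(spins = blocks, cell_types = types,
         volumes = rep(16, 36), attempts = 0,
         initial_in_cluster = blocks > 0), class = "cpm_state")
  p <- cpm_params(grid = c(24L, 24L), n_cells = 36L)

  # concentric-like sorted layout: C1 in one corner block
  sorted_types <- rep(2L, 36)
  sorted_types[c(1, 2, 7, 8, 13, 14)] <- 1L   # compact patch
  mi_sorted <- mixing_index(mk(sorted_types), p)

  # checkerboard: maximal heterotypic contact
  cb <- ifelse((matrix(0:35, 6, 6) %% 6 + 0:35 %/% 6) %% 2 == 0, 1L, 2L)
  mi_cb <- mixing_index(mk(as.vector(cb)), p)
  expect_gt(mi_cb, 1)
  expect_lt(mi_sorted, mi_cb)

  # random shuffles of the same geometry average to ~1
  set.seed(5)
  mi_rand <- mean(replicate(60,
    mixing_index(mk(sample(sorted_types)), p)))
  expect_equal(mi_rand, 1, tolerance = 0.1)

  # absent type is flagged
  expect_warning(val <- mixing_index(mk(rep(1L, 36)), p),
                 class = "cpm_metric_warning")
  expect_true(is.na(val))
})

test_that("invasion fraction counts volume outside the dilated footprint", {
  p <- condition_params("baseline", "desk")
  st <- init_state(p)
  f0 <- ecm_invasion_fraction(st, st$initial_in_cluster)
  expect_equal(unname(f0), c(0, 0))

  # hand-move 10 sites of a core cell far outside
  st2 <- st
  core_id <- which(st$cell_types == 1L)[1]
  sites <- which(st2$spins == core_id)[1:10]
  st2$spins[sites] <- 0L
  st2$spins[1:10, 95] <- core_id
  n_c1 <- sum(st2$spins %in% which(st$cell_types == 1L))
  f2 <- ecm_invasion_fraction(st2, st$initial_in_cluster)
  expect_equal(unname(f2["C1"]), 10 / n_c1)
  expect_equal(unname(f2["C2"]), 0)
})

test_that("frozen dynamics reject the exponent fit with a flag", {
  # relax to a zero-temperature minimum first, then watch it: with J = 0
  # and volumes at target every move is uphill, so nothing moves
  p <- cpm_params(grid = c(60L, 60L), n_cells = 10L, core_fraction = 0.3,
                  J = dispersim:::j_table(0, 0, 0, 0, 0),
                  lambda_volume = 1, V_target = 16, temperature = 0,
                  n_mcs = 2e5, record_every = 2e5, seed = 3L)
  relaxed <- run_cpm(p)$state
  p2 <- p; p2$n_mcs <- 4000; p2$record_every <- 100
  res <- run_cpm(p2, state = relaxed)
  out <- simulated_msd(res, "C1")
  expect_true(isTRUE(out$rejected))
  expect_match(out$reason, "insufficient|lag|pairs|displacement")

  expect_error(simulated_msd(structure(list(snapshots = list(1, 2)),
                                       class = "cpm_result"), "C1"),
               class = "input_error")
})

test_that("qualitative dispersal claims survive a +-25% energy sweep", {
  for (js in c(0.75, 1.25)) {
    inv_c <- inv_b <- mix_l <- mix_b <- numeric(3)
    for (s in 1:3) {
      rc <- suppressWarnings(run_cpm(condition_params("combined", "desk",
                                                      seed = s,
                                                      j_scale = js)))
      rb <- suppressWarnings(run_cpm(condition_params("baseline", "desk",
                                                      seed = s,
                                                      j_scale = js)))
      rl <- suppressWarnings(run_cpm(condition_params("low_adhesion",
                                                      "desk", seed = s,
                                                      j_scale = js)))
      inv_c[s] <- cpm_summary(rc)$invasion_C1
      inv_b[s] <- cpm_summary(rb)$invasion_C1
      mix_l[s] <- cpm_summary(rl)$mixing
      mix_b[s] <- cpm_summary(rb)$mixing
    }
    expect_gt(mean(inv_c), mean(inv_b))
    expect_gt(mean(mix_l), mean(mix_b))
  }
})

test_that("different seeds give statistically equivalent baseline energies", {
  final_energy <- function(seed) {
    res <- suppressWarnings(run_cpm(condition_params("baseline", "desk",
                                                     seed = seed)))
    tail(res$metrics$energy, 1)
  }
  e1 <- vapply(1:6, final_energy, numeric(1))
  e2 <- vapply(101:106, final_energy, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(e1, e2)$p.value), 0.01)
})
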