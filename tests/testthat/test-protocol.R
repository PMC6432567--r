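# Small threaded systems: N = 8..16 with reduced salt so the checks run at
# interactive speed; the production ion content is exercised by the
# acceptance suite.

test_that("initial threading places the chain and ions correctly", {
  g <- small_geom()
  cfg <- pt_run_config(N = 16, E = 0, n_salt_cations = 16,
                       n_salt_anions = 16, seed = 2)
  st <- pt_init_system(cfg, g)
  # monomer 1 just at the trans-side opening, on the axis
  expect_lt(abs(st$positions[1, 3] - g$z_hi), 0.5)
  expect_equal(st$positions[1, 1], g$axis_x, tolerance = 1e-9)
  expect_equal(sum(st$charge), 0)
  expect_equal(st$n_monomer, 16)
  # packing validity: minimum-image pair separation >= 0.8
  p <- st$positions
  n <- nrow(p)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    d <- abs(sweep(p[(i + 1):n, , drop = FALSE], 2, p[i, ]))
    for (k in 1:3) d[, k] <- pmin(d[, k], g$box[k] - d[, k])
    dmin <- min(dmin, sqrt(min(rowSums(d^2))))
  }
  expect_gte(dmin, 0.8)
  # identical seed reproduces the same configuration
  st2 <- pt_init_system(cfg, g)
  expect_identical(st$positions, st2$positions)
})

test_that("tethered equilibration holds monomer 1, relaxes bonds, thermostats", {
  g <- small_geom()
  cfg <- pt_run_config(N = 16, E = 0, n_salt_cations = 16,
                       n_salt_anions = 16, seed = 3,
                       equilibration_steps = 8000, frame_every = 50)
  st <- pt_init_system(cfg, g)
  eq <- pt_equilibrate(st, cfg, g, dt = 0.002)
  tr <- eq$traj
  # tether contract: monomer 1 never moves
  z1 <- tr$frames[, 1, ]
  expect_equal(max(abs(z1 - z1[, 1])), 0)
  # 1D Boltzmann oracle for the bond: <r> ~ r0 + 2 kT/(k r0) plus the
  # electrostatic stretch; well inside [1.00, 1.02] at k = 600, T = 1
  expect_gt(eq$equil$mean_bond, 1.00)
  expect_lt(eq$equil$mean_bond, 1.02)
  expect_equal(eq$equil$kinetic_T, 1.0, tolerance = 0.03)
})

test_that("driven runs complete, keep charge, and never back-thread", {
  g <- small_geom()
  taus <- c()
  for (seed in 1:3) {
    cfg <- pt_run_config(N = 8, E = 16, n_salt_cations = 16,
                         n_salt_anions = 16, seed = seed,
                         equilibration_steps = 1500, frame_every = 50,
                         max_steps = 200000)
    st <- pt_init_system(cfg, g)
    eq <- pt_equilibrate(st, cfg, g, relax_zeta = 1)
    res <- pt_run_translocation(eq$state, cfg, g)
    expect_true(res$completed)
    expect_gt(res$tau, 0)
    taus <- c(taus, res$tau)
    tr <- res$traj
    # conservation of particle count and charge
    expect_equal(dim(tr$frames)[2], nrow(st$positions))
    expect_equal(sum(tr$charge), 0)
    # region counts sum to N at every frame (errors inside if violated)
    cnt <- pt_monomer_counts(tr)
    expect_true(all(cnt$I + cnt$II + cnt$III == 8))
    # the last frame of a completed run has every monomer in trans
    expect_equal(cnt$III[nrow(cnt)], 8)
    # barrier contract: once monomer 1 has cleared the exit it stays trans
    z1 <- tr$frames[3, 1, ]
    past <- which(z1 > tr$z_hi + 2^(1 / 6))
    if (length(past))
      expect_true(all(z1[min(past):length(z1)] > tr$z_hi))
  }
  expect_equal(length(unique(round(taus, 6))), 3)  # independent runs differ
})

test_that("ensemble-mean translocation progress is nondecreasing", {
  g <- small_geom()
  series <- list()
  for (seed in 11:13) {
    cfg <- pt_run_config(N = 8, E = 16, n_salt_cations = 8,
                         n_salt_anions = 8, seed = seed,
                         equilibration_steps = 1000, frame_every = 50,
                         max_steps = 200000)
    st <- pt_init_system(cfg, g)
    eq <- pt_equilibrate(st, cfg, g, relax_zeta = 1)
    res <- pt_run_translocation(eq$state, cfg, g)
    series[[length(series) + 1]] <-
      { s <- pt_s_series(res$traj); list(time = s$time, value = s$s,
                                         tau = s$tau) }
  }
  cur <- pt_ensemble_curves(series, t_grid = seq(0, 1, by = 0.05))
  # monotone within noise: allow small dips against the spread
  dips <- diff(cur$mean)
  expect_true(all(dips > -pmax(cur$spread[-1], 0.5)))
  expect_gt(tail(cur$mean, 1), cur$mean[1])
})
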