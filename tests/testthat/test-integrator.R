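test_that("zero-friction limit conserves energy (symplectic check)", {
  g <- open_geom()
  st <- pt_state(rbind(c(6, 6, 10), c(6, 6, 11.2)), charge = c(0, 0),
                 species = rep("neutral", 2))
  lp <- pt_langevin_params(dt = 0.001, seed = 7, zeta = 0, T = 1)
  out <- pt_run_dynamics(st, pt_bond_topology(2), g, lp = lp,
                         n_steps = 100000, frame_every = 7,
                         record_energy = TRUE)
  E <- out$traj$energy
  n <- length(E)
  h1 <- mean(E[2:(n %/% 2)])
  h2 <- mean(E[(n %/% 2 + 1):n])
  expect_lt(abs(h2 - h1) / abs(h1), 1e-4)
})

test_that("free beads equilibrate to the target temperature (equipartition)", {
  g <- open_geom()
  set.seed(2)
  st <- pt_state(matrix(runif(90, 1, 11), 30, 3), charge = rep(0, 30),
                 species = rep("neutral", 30))
  lp <- pt_langevin_params(dt = 0.005, seed = 3, zeta = 1, T = 1)
  out <- pt_run_dynamics(st, NULL, g, lp = lp, n_steps = 50000,
                         frame_every = 25)
  Tbar <- mean(out$traj$temp[-(1:200)])
  expect_equal(Tbar, 1.0, tolerance = 0.02)
})

test_that("thermostat holds on an interacting charged system", {
  g <- open_geom()
  st <- ion_gas(16, g, seed = 4)
  lp <- pt_langevin_params(dt = 0.002, seed = 11, zeta = 1, T = 1)
  out <- pt_run_dynamics(st, NULL, g, lp = lp, n_steps = 50000,
                         frame_every = 50)
  expect_equal(mean(out$traj$temp[-(1:100)]), 1.0, tolerance = 0.02)
})

test_that("velocity autocorrelation decays like the Ornstein-Uhlenbeck law", {
  g <- open_geom()
  st <- pt_state(matrix(c(6, 6, 20), 1, 3), charge = 0, species = "neutral")
  lag_steps <- 20                      # lag = 0.1 tau_u at dt = 0.005
  segs <- 1500
  V <- matrix(0, segs + 1, 3)
  cur <- st
  for (k in seq_len(segs + 1)) {
    V[k, ] <- cur$velocities
    lp <- pt_langevin_params(dt = 0.005, seed = 13 + k, zeta = 1, T = 1)
    cur <- pt_run_dynamics(cur, NULL, g, lp = lp, n_steps = lag_steps,
                           frame_every = lag_steps)$state
  }
  v0 <- V[1:segs, ]
  v1 <- V[2:(segs + 1), ]
  corr <- sum(v0 * v1) / sqrt(sum(v0^2) * sum(v1^2))
  expect_equal(corr, exp(-lag_steps * 0.005), tolerance = 0.03)
})

test_that("trajectories are deterministic given the seed", {
  g <- open_geom()
  st <- ion_gas(8, g, seed = 5)
  lp <- pt_langevin_params(dt = 0.005, seed = 42)
  o1 <- pt_run_dynamics(st, NULL, g, lp = lp, n_steps = 200, frame_every = 50)
  o2 <- pt_run_dynamics(st, NULL, g, lp = lp, n_steps = 200, frame_every = 50)
  expect_identical(o1$state$positions, o2$state$positions)
  expect_identical(o1$traj$frames, o2$traj$frames)
  o3 <- pt_run_dynamics(st, NULL, g,
                        lp = pt_langevin_params(dt = 0.005, seed = 43),
                        n_steps = 200, frame_every = 50)
  expect_false(identical(o1$state$positions, o3$state$positions))
})

test_that("kinetic temperature follows its definition", {
  st <- pt_state(matrix(1, 4, 3), velocities = matrix(0, 4, 3),
                 charge = rep(0, 4), species = rep("neutral", 4))
  expect_equal(pt_kinetic_temperature(st), 0)
  v <- matrix(1, 4, 3)    # every speed sqrt(3), m = 1
  st2 <- pt_state(matrix(1, 4, 3), velocities = v, charge = rep(0, 4),
                  species = rep("neutral", 4))
  expect_equal(pt_kinetic_temperature(st2), 1.0)
})

test_that("the dt policy tightens with field strength", {
  expect_equal(pt_default_dt(0.5), 0.005)
  expect_equal(pt_default_dt(4), 0.001)
  expect_equal(pt_default_dt(32), 5e-4)
  expect_error(pt_langevin_params(dt = 0), "positive")
})
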