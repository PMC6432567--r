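test_that("zero charges give zero energy and forces", {
  box <- c(10, 10, 10)
  pos <- matrix(runif(12, 0, 10), 4, 3)
  r <- pt_ewald(pos, rep(0, 4), box)
  expect_equal(r$energy, 0, tolerance = 1e-14)
  expect_equal(max(abs(r$forces)), 0, tolerance = 1e-14)
})

test_that("an isolated pair in a huge box recovers the bare Coulomb limit", {
  box <- c(100, 100, 100)
  pos <- rbind(c(50, 50, 50), c(50, 50, 53))
  r <- pt_ewald(pos, c(1, -1), box)
  expect_equal(r$energy, -1.0, tolerance = 1e-2)
  # force magnitude lambda_B / r^2 = 3/9
  expect_equal(abs(r$forces[1, 3]), 1 / 3, tolerance = 1e-2)
})

test_that("direct-sum oracle: single image equals the bare pair form", {
  box <- c(50, 50, 50)
  pos <- rbind(c(10, 10, 10), c(10, 10, 14))
  e0 <- pt_direct_sum(pos, c(1, -1), box, n_images = 0)
  expect_equal(e0, pt_coulomb(4, 1, -1), tolerance = 1e-12)
})

test_that("direct-sum partial sums converge with shell count", {
  cfg <- random_charges(8, 10, seed = 5)
  ps <- pt_direct_sum(cfg$pos, cfg$q, cfg$box, n_images = 10, partial = TRUE)
  # Cauchy differences shrink beyond the first shells
  d <- abs(diff(ps))
  expect_lt(mean(tail(d, 3)), mean(d[2:4]))
  expect_lt(tail(d, 1), 1e-2)
})

test_that("Ewald matches the direct-sum oracle on random neutral systems", {
  worst <- 0
  for (s in 1:20) {
    n <- sample(c(16, 24, 32), 1)
    cfg <- random_charges(n, L = 10 + s %% 5, seed = 100 + s)
    ew <- pt_ewald_params(cfg$box)
    e <- pt_ewald(cfg$pos, cfg$q, cfg$box, ew, dipole_correction = TRUE)
    ed <- pt_direct_sum(cfg$pos, cfg$q, cfg$box, n_images = 8)
    rel <- abs(e$energy - ed) / max(abs(ed), 1)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-3)
})

test_that("NaCl-like cubic motif agrees between Ewald and the oracle", {
  a <- 2
  g <- expand.grid(x = c(0, a), y = c(0, a), z = c(0, a))
  pos <- as.matrix(g) + 4
  q <- (-1)^(g$x / a + g$y / a + g$z / a)
  box <- c(4 * a, 4 * a, 4 * a)
  e <- pt_ewald(pos, q, box, dipole_correction = TRUE)
  ed <- pt_direct_sum(pos, q, box, n_images = 10)
  expect_equal(e$energy, ed, tolerance = 1e-2)
})

test_that("energy is invariant under the real/reciprocal split and rigid shifts", {
  cfg <- random_charges(24, 12, seed = 9)
  e1 <- pt_ewald(cfg$pos, cfg$q, cfg$box, pt_ewald_params(cfg$box))
  e2 <- pt_ewald(cfg$pos, cfg$q, cfg$box,
                 pt_ewald_params(cfg$box, r_cut = 4))
  expect_equal(e1$energy, e2$energy,
               tolerance = 1e-3 * max(1, abs(e1$energy)))
  shift <- c(1.7, -2.3, 5.1)
  pos2 <- sweep(cfg$pos, 2, -shift) %% 12
  e3 <- pt_ewald(pos2, cfg$q, cfg$box, pt_ewald_params(cfg$box))
  expect_equal(e1$energy, e3$energy,
               tolerance = 1e-3 * max(1, abs(e1$energy)))
})

test_that("Ewald forces match central differences of the Ewald energy", {
  cfg <- random_charges(16, 11, seed = 21)
  ew <- pt_ewald_params(cfg$box)
  r <- pt_ewald(cfg$pos, cfg$q, cfg$box, ew)
  h <- 1e-5
  for (i in c(1, 8)) for (k in 1:3) {
    pp <- cfg$pos; pp[i, k] <- pp[i, k] + h
    pm <- cfg$pos; pm[i, k] <- pm[i, k] - h
    fn <- -(pt_ewald(pp, cfg$q, cfg$box, ew)$energy -
            pt_ewald(pm, cfg$q, cfg$box, ew)$energy) / (2 * h)
    expect_equal(r$forces[i, k], fn, tolerance = 1e-4 * max(1, abs(fn)))
  }
})

test_that("non-neutral systems and inconsistent cutoffs are rejected", {
  pos <- matrix(runif(9, 0, 5), 3, 3)
  expect_error(pt_ewald(pos, c(1, 1, -1.5), c(5, 5, 5)), "neutral")
  expect_error(pt_ewald_params(c(5, 5, 5), r_cut = 4), "half the smallest")
  expect_error(pt_ewald_params(c(5, 5, 5), accuracy = 2), "accuracy")
})
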