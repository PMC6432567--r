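test_that("WCA potential matches its closed form and is continuous at the cutoff", {
  rc <- 2^(1 / 6)
  expect_equal(pt_wca(rc)$energy, 0, tolerance = 1e-12)
  expect_equal(pt_wca(rc)$force, 0, tolerance = 1e-10)
  expect_equal(pt_wca(1.0, sigma = 1, eps = 1.2)$energy, 1.2)
  expect_equal(pt_wca(3.0)$energy, 0)
  expect_equal(pt_wca(3.0)$force, 0)
  # both branches -> 0 approaching the cutoff from below
  r <- rc * (1 - 10^seq(-8, -6))
  expect_true(all(abs(pt_wca(r)$energy) < 1e-10))
  expect_error(pt_wca(0), "positive")
  expect_error(pt_wca(-1), "positive")
})

test_that("harmonic bond energy, force and sign convention", {
  p <- pt_model_params()
  expect_equal(pt_bond(1.0, p)$energy, 0)
  expect_equal(pt_bond(1.0, p)$force, 0)
  expect_equal(pt_bond(2.0, p)$energy, 300)
  expect_equal(pt_bond(0.5, p)$force, 300)  # compressed bond pushes out
  expect_error(pt_bond(-0.1, p), "nonnegative")
})

test_that("bare Coulomb form: thermal energy at the Bjerrum length", {
  expect_equal(pt_coulomb(3.0, 1, 1, lambda_B = 3.0), 1.0)
  expect_equal(pt_coulomb(3.0, 1, -1, lambda_B = 3.0), -1.0)
  expect_equal(pt_coulomb(6.0, 1, 1, lambda_B = 3.0), 0.5)
  expect_error(pt_coulomb(0, 1, 1), "positive")
})

test_that("radial force equals -dU/dr for every pair potential", {
  set.seed(1)
  h <- 1e-6
  r <- runif(100, 0.7, 1.3)
  num <- -(pt_wca(r + h)$energy - pt_wca(r - h)$energy) / (2 * h)
  expect_equal(pt_wca(r)$force, num, tolerance = 1e-5)
  r2 <- runif(100, 0.5, 2)
  p <- pt_model_params()
  num2 <- -(pt_bond(r2 + h, p)$energy - pt_bond(r2 - h, p)$energy) / (2 * h)
  expect_equal(pt_bond(r2, p)$force, num2, tolerance = 1e-5)
  r3 <- runif(100, 1, 10)
  num3 <- -(pt_coulomb(r3 + h, 1, 1) - pt_coulomb(r3 - h, 1, 1)) / (2 * h)
  fc <- 3 / r3^2   # analytic -dU/dr of lambda_B Zi Zj / r
  expect_equal(fc, num3, tolerance = 1e-5)
})

test_that("two neutral bonded beads at the rest length feel no force", {
  g <- open_geom()
  st <- pt_state(rbind(c(6, 6, 10), c(6, 6, 11)), charge = c(0, 0),
                 species = rep("neutral", 2))
  f <- pt_forces(st, pt_bond_topology(2), g)
  expect_equal(max(abs(f$forces)), 0, tolerance = 1e-12)
  expect_equal(f$energy, 0, tolerance = 1e-12)
})

test_that("internal forces of a charged cluster obey the third law", {
  g <- open_geom()
  set.seed(3)
  for (rep in 1:3) {
    pos <- cbind(runif(10, 2, 10), runif(10, 2, 10), runif(10, 5, 30))
    q <- rep(c(-1, 1), 5)
    st <- pt_state(pos, charge = q,
                   species = ifelse(q > 0, "cation", "anion"))
    f <- pt_forces(st, NULL, g)
    expect_lt(max(abs(colSums(f$forces))), 1e-10)
  }
})

test_that("assembled force matches the finite-difference energy gradient", {
  g <- small_geom()
  set.seed(4)
  pos <- cbind(runif(10, 1, 15), runif(10, 1, 15), runif(10, 2, 20))
  q <- rep(c(-1, 1), 5)
  sp <- ifelse(q > 0, "cation", "anion")
  st <- pt_state(pos, charge = q, species = sp)
  ew <- pt_ewald_params(g$box)
  f <- pt_forces(st, NULL, g, ewald = ew)
  h <- 1e-5
  for (i in c(2, 7)) {
    for (k in 1:3) {
      pp <- pos; pp[i, k] <- pp[i, k] + h
      pm <- pos; pm[i, k] <- pm[i, k] - h
      ep <- pt_forces(pt_state(pp, charge = q, species = sp), NULL, g,
                      ewald = ew)$energy
      em <- pt_forces(pt_state(pm, charge = q, species = sp), NULL, g,
                      ewald = ew)$energy
      fn <- -(ep - em) / (2 * h)
      expect_equal(f$forces[i, k], fn,
                   tolerance = 1e-5 * max(1, abs(fn)))
    }
  }
})

test_that("overlapping beads raise a singular-configuration error", {
  g <- open_geom()
  st <- pt_state(rbind(c(6, 6, 10), c(6, 6, 10)), charge = c(1, -1),
                 species = c("cation", "anion"))
  expect_error(pt_forces(st, NULL, g), "singular")
})

test_that("parameter bundle validates positivity and carries the defaults", {
  p <- pt_model_params()
  expect_equal(p$sigma_bb, 1.0)
  expect_equal(p$eps_bb, 1.2)
  expect_equal(p$sigma_bw, 1.5)
  expect_equal(p$eps_bw, 2.5)
  expect_equal(p$k_bond, 600)
  expect_equal(p$r0, 1.0)
  expect_equal(p$lambda_B, 3.0)
  expect_equal(p$zeta, 1.0)
  expect_equal(p$T, 1.0)
  expect_error(pt_model_params(eps_bb = -1), "eps_bb")
  expect_error(pt_model_params(lambda_B = 0), "lambda_B")
})

test_that("state constructor enforces chain layout and electroneutrality", {
  expect_error(pt_state(matrix(0, 2, 3), charge = c(1, 1),
                        species = c("cation", "cation")),
               "electroneutrality")
  expect_error(pt_state(matrix(runif(9), 3, 3), charge = c(1, -1, 0),
                        species = c("cation", "monomer", "neutral")),
               "contiguous")
  topo <- pt_bond_topology(5)
  expect_equal(nrow(topo$bonds), 4)
  expect_true(all(topo$bonds[, 2] - topo$bonds[, 1] == 1))
})
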