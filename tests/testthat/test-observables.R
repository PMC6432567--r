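test_that("translocation-time width matches the Gaussian 1/e analytic form", {
  set.seed(8)
  s <- 2.5
  taus <- rnorm(4000, mean = 50, sd = s)
  st <- pt_translocation_stats(taus)
  expect_equal(st$mean, 50, tolerance = 0.01)
  expect_equal(st$w, 2 * sqrt(2) * s, tolerance = 0.06 * 2 * sqrt(2) * s)
  expect_equal(st$ratio, st$w / st$mean, tolerance = 1e-12)
})

test_that("degenerate and small translocation-time samples are handled", {
  st <- pt_translocation_stats(rep(7, 40))
  expect_equal(st$w, 0)
  expect_equal(st$ratio, 0)
  expect_error(pt_translocation_stats(c(1)), "insufficient")
})

test_that("the 1/e width of a bimodal distribution follows the density scan", {
  set.seed(9)
  taus <- c(rnorm(3000, 20, 1), rnorm(3000, 28, 1))
  st <- pt_translocation_stats(taus)
  # independent brute-force scan of the same estimated density
  d <- st$density
  thr <- max(d$y) / exp(1)
  above <- range(d$x[d$y >= thr])
  expect_equal(st$w, diff(above), tolerance = 0.1)
  # both lobes lie above threshold: w spans them plus the gap
  expect_gt(st$w, 8)
})

test_that("alpha fit recovers exact power laws and two-point slopes", {
  d <- data.frame(N = c(32, 64, 128, 256), tau = 2 * c(32, 64, 128, 256)^1.3)
  f <- pt_fit_alpha(d)
  expect_equal(f$exponent, 1.3, tolerance = 1e-10)
  expect_lt(f$stderr, 1e-10)
  d2 <- d[1:2, ]
  f2 <- pt_fit_alpha(d2)
  expect_equal(f2$exponent, log(d2$tau[2] / d2$tau[1]) / log(2),
               tolerance = 1e-12)
  expect_error(pt_fit_alpha(data.frame(N = 2, tau = 1)), "at least 2")
  expect_error(pt_fit_alpha(data.frame(N = c(2, 4), tau = c(-1, 1))),
               "positive")
})

test_that("delta fits split into regimes and flip the slope sign", {
  E <- c(0.2, 0.5, 1, 2, 4, 8, 10, 16, 32)
  d <- data.frame(E = E, tau = 100 / E)
  f <- pt_fit_delta(d)
  for (r in names(f)) expect_equal(f[[r]]$exponent, 1, tolerance = 1e-10)
  # piecewise with distinct exponents, continuous at the breaks
  delta <- c(1.04, 1.64, 1.0)
  tau <- ifelse(E <= 1, E^-delta[1],
                ifelse(E <= 10, E^-delta[2], 10^-delta[2] *
                         (E / 10)^-delta[3]))
  f2 <- pt_fit_delta(data.frame(E = E, tau = tau))
  expect_equal(f2$weak$exponent, 1.04, tolerance = 1e-6)
  expect_equal(f2$intermediate$exponent, 1.64, tolerance = 1e-6)
  expect_equal(f2$strong$exponent, 1.0, tolerance = 1e-6)
  expect_warning(pt_fit_delta(data.frame(E = c(2, 4), tau = c(3, 2))),
                 "skipped")
})

test_that("radius of gyration matches closed forms by region", {
  # all monomers at one point
  fr <- array(0, c(3, 4, 1))
  fr[, , 1] <- rbind(rep(5, 4), rep(5, 4), rep(120, 4))
  tr <- fake_traj(fr, time = 0, n_monomer = 4)
  expect_equal(unname(pt_frame_rg(tr, 1)["III"]), 0)
  expect_true(is.na(pt_frame_rg(tr, 1)["I"]))   # empty region -> missing
  # two monomers separated by d -> d/2
  fr2 <- array(0, c(3, 2, 1))
  fr2[, , 1] <- rbind(c(5, 5), c(5, 5), c(110, 116))
  tr2 <- fake_traj(fr2, time = 0, n_monomer = 2)
  expect_equal(unname(pt_frame_rg(tr2, 1)["III"]), 3)
  # rigid rod of N beads, spacing 1: Rg = sqrt((N^2 - 1) / 12)
  N <- 21
  fr3 <- array(0, c(3, N, 1))
  fr3[1, , 1] <- 10; fr3[2, , 1] <- 10; fr3[3, , 1] <- 110 + seq_len(N)
  tr3 <- fake_traj(fr3, time = 0, n_monomer = N)
  expect_equal(unname(pt_frame_rg(tr3, 1)["tot"]), sqrt((N^2 - 1) / 12),
               tolerance = 1e-12)
})

test_that("chain-end curves are measured from the exit plane and are linear in the mean", {
  N <- 3
  nf <- 5
  fr <- array(0, c(3, N + 1, nf))
  for (f in seq_len(nf)) {
    fr[3, 1, f] <- 102.25 + (f - 1) * 2   # z1 walks into trans
    fr[3, 2, f] <- 100
    fr[3, 3, f] <- 95
    fr[3, 4, f] <- 10                      # one ion
  }
  tr <- fake_traj(fr, time = seq(0, 1, length.out = nf), n_monomer = N,
                  tau = 1)
  ce <- pt_chain_ends(list(tr), t_grid = seq(0, 1, by = 0.25))
  expect_equal(ce$z1$mean[1], 0)                   # on the exit plane
  expect_equal(ce$z1$mean[5], 8)
  expect_equal(ce$z1_zN$mean, ce$z1$mean - ce$zN$mean, tolerance = 1e-12)
})

test_that("monomer counts match a hand-built straddling configuration", {
  z <- c(96, 97.75, 100, 102.25, 110)     # I, II(boundary), II, II(boundary), III
  fr <- array(0, c(3, 5, 1))
  fr[3, , 1] <- z
  tr <- fake_traj(fr, time = 0, n_monomer = 5)
  cnt <- pt_monomer_counts(tr)
  expect_equal(unlist(cnt[1, c("I", "II", "III")], use.names = FALSE),
               c(1, 3, 1))
})

test_that("MSD of deterministic drift is exactly quadratic with beta = 2", {
  runs <- lapply(1:12, function(i) pt_synth_s_traj(64, beta_true = 2,
                                                   n_steps = 100, seed = i,
                                                   noise = 0))
  m <- pt_translocation_msd(runs)
  expect_equal(m$fit$exponent, 2, tolerance = 1e-8)
  # endpoint identity: MSD(1) = (N - 1)^2 for runs starting at s = 1
  expect_equal(tail(m$curve$mean, 1), 63^2, tolerance = 1e-8)
  expect_error(pt_translocation_msd(runs, fit_window = c(0.5, 1.5)),
               "inside")
})

test_that("synthetic late-time exponent is recovered within 2 stderr", {
  runs <- lapply(1:200, function(i) pt_synth_s_traj(128, beta_true = 1.5,
                                                    n_steps = 120, seed = i))
  m <- pt_translocation_msd(runs)
  expect_lt(abs(m$fit$exponent - 1.5), 2 * max(m$fit$stderr, 0.02))
})

test_that("condensation counting matches the criterion edge and the oracle", {
  # no ions near the chain
  fr0 <- pt_synth_condensation(0, 10, seed = 2)
  c0 <- pt_condensation(fr0)
  expect_equal(sum(c0$Nc_plus) + sum(c0$Nc_minus), 0)
  expect_equal(c0$Qc, 0)
  # one counterion at 2.9 < 3 from a region-III monomer
  N <- 8
  pos <- rbind(cbind(rep(20, N), rep(20, N), 110 + seq_len(N)),
               c(20, 22.9, 111))
  fr1 <- list(pos = pos, charge = c(rep(-1, N), 1),
              species = c(rep("monomer", N), "counterion"),
              n_monomer = N, box = c(40, 40, 200), z_lo = 97.75,
              z_hi = 102.25)
  c1 <- pt_condensation(fr1)
  expect_equal(unname(c1$Nc_plus["III"]), 1)
  expect_equal(c1$Qc, 1)
  # randomized frames agree with the O(n^2) scalar oracle exactly
  for (s in 1:5) {
    nc <- sample(0:12, 1); nf_ <- sample(0:12, 1)
    fr <- pt_synth_condensation(nc, nf_, seed = 100 + s)
    got <- pt_condensation(fr)
    oracle <- condensation_oracle(fr)
    expect_identical(sum(got$Nc_plus), unname(oracle["plus"]))
    expect_identical(sum(got$Nc_minus), unname(oracle["minus"]))
    expect_equal(sum(got$Nc_plus), nc)
  }
})

test_that("Manning reference density is e over the Bjerrum length", {
  expect_equal(pt_manning_reference(3.0), 1 / 3)
  expect_equal(pt_manning_reference(1.0), 1.0)
  expect_equal(pt_manning_reference(2.0), 0.5)
  expect_error(pt_manning_reference(0), "positive")
})

test_that("contour length and effective line density follow their formulas", {
  N <- 128
  pos <- cbind(rep(10, N), rep(10, N), 30 + seq_len(N))
  fr <- list(pos = pos, charge = rep(-1, N), species = rep("monomer", N),
             n_monomer = N, box = c(200, 200, 400), z_lo = -2, z_hi = -1)
  # no ions: l = 127, density N/l
  ld <- pt_line_density(fr)
  expect_equal(ld$contour, 127)
  expect_equal(ld$density, 128 / 127)
  # complete neutralization: one condensed counterion per monomer
  N2 <- 8
  pos2 <- rbind(cbind(rep(10, N2), rep(10, N2), 30 + seq_len(N2)),
                cbind(rep(11, N2), rep(10, N2), 30 + seq_len(N2)))
  fr2 <- list(pos = pos2, charge = c(rep(-1, N2), rep(1, N2)),
              species = c(rep("monomer", N2), rep("counterion", N2)),
              n_monomer = N2, box = c(200, 200, 400), z_lo = -2, z_hi = -1)
  expect_equal(pt_line_density(fr2)$density, 0)
})

test_that("z profiles normalize and localize correctly", {
  N <- 6
  fr <- array(0, c(3, N + 2, 1))
  fr[3, 1:N, 1] <- 80.2                  # all monomers at one z
  fr[3, N + 1, 1] <- 120; fr[3, N + 2, 1] <- 30
  tr <- fake_traj(fr, time = 0, n_monomer = N,
                  charge = c(rep(-1, N), 1, -1),
                  species = c(rep("monomer", N), "counterion", "anion"),
                  tau = 1)
  pr <- pt_z_profiles(list(tr), t_windows = 0)[["0"]]
  expect_equal(sum(pr$P_m * 0.5), 1, tolerance = 1e-12)  # unit integral
  expect_equal(sum(pr$P_m > 0), 1)                        # single bin
  expect_equal(pr$z[which.max(pr$P_m)], 80.25)
  expect_warning(pt_z_profiles(list(tr), t_windows = 0.9), "no frames")
})

test_that("density map marginal over y reproduces the z profile", {
  set.seed(10)
  N <- 40
  nf <- 6
  fr <- array(0, c(3, N, nf))
  for (f in seq_len(nf)) {
    fr[1, , f] <- runif(N, 0, 48)
    fr[2, , f] <- runif(N, 0, 49.36)
    fr[3, , f] <- runif(N, 90, 130)
  }
  tr <- fake_traj(fr, time = seq(0, 1, length.out = nf), n_monomer = N,
                  charge = rep(0, N), species = rep("monomer", N), tau = 1)
  dm <- pt_density_map(list(tr), cell = 0.5)
  pr <- pt_z_profiles(list(tr), t_windows = 0, width = 1)[["0"]]
  marg <- colSums(dm$density)
  marg <- marg / (sum(marg) * 0.5)
  nz <- pr$P_m > 0 | marg[seq_along(pr$P_m)] > 0
  expect_equal(marg[seq_along(pr$P_m)][nz], pr$P_m[nz], tolerance = 1e-9)
  # single static bead occupies exactly one cell
  fr1 <- array(c(5, 5, 100), c(3, 1, 1))
  tr1 <- fake_traj(fr1, time = 0, n_monomer = 1, charge = 0,
                   species = "monomer", tau = 1)
  dm1 <- pt_density_map(list(tr1))
  expect_equal(sum(dm1$density > 0), 1)
})

test_that("ensemble curves are invariant under run reordering", {
  runs <- lapply(1:10, function(i) pt_synth_s_traj(32, 1.6, seed = i))
  series <- lapply(runs, function(r) list(time = r$time, value = r$s,
                                          tau = r$tau))
  c1 <- pt_ensemble_curves(series)
  c2 <- pt_ensemble_curves(rev(series))
  expect_equal(c1$mean, c2$mean, tolerance = 1e-12)
  # split halves agree within the standard error of the mean
  ca <- pt_ensemble_curves(series[1:5])
  cb <- pt_ensemble_curves(series[6:10])
  sem <- c1$spread / sqrt(5)
  mid <- c1$t_grid > 0.2 & c1$t_grid < 0.9
  expect_true(mean(abs(ca$mean - cb$mean)[mid] <= 4 * pmax(sem[mid], 0.5))
              > 0.9)
})
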