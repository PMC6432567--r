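#' Specification of a synthetic translocation ensemble
#'
#' Ground-truth harness for the scaling-analysis estimators: the generators
#' below draw data whose statistical structure matches what the analysis
#' assumes (single-peaked positive translocation times with median
#' `c0 N^alpha E^-delta`; monotone-on-average translocation coordinates
#' with late-time MSD exponent beta), without emulating any force-field
#' physics.
#'
#' @param alpha_true,delta_true,beta_true ground-truth exponents (positive)
#' @param noise_cv coefficient of variation of the translocation times
#' @param N_list,E_list chain-length and field grids
#' @param n_runs runs per (N, E) cell
#' @param seed integer seed (every generator is deterministic given it)
#' @param c0 scale prefactor of the median translocation time
#' @return object of class `pt_synth_spec`
#' @export
pt_synth_spec <- function(alpha_true = 1.3, delta_true = 1.3,
                          beta_true = 2 / alpha_true, noise_cv = 0.1,
                          N_list = c(64, 128, 256, 384),
                          E_list = c(0.5, 2, 8), n_runs = 50, seed = 1,
                          c0 = 1.0) {
  stopifnot(alpha_true > 0, delta_true > 0, beta_true > 0, noise_cv >= 0)
  structure(list(alpha_true = alpha_true, delta_true = delta_true,
                 beta_true = beta_true, noise_cv = noise_cv,
                 N_list = N_list, E_list = E_list, n_runs = n_runs,
                 seed = seed, c0 = c0),
            class = "pt_synth_spec")
}

#' Synthetic translocation-time samples
#'
#' Times are lognormal with median `c0 N^alpha E^-delta` and shape set by
#' the coefficient of variation (`sdlog = sqrt(log(1 + cv^2))`): positive
#' support and a single peak, near-Gaussian at small cv. `noise_cv = 0`
#' returns the median exactly.
#'
#' @param spec a [pt_synth_spec()]
#' @return data frame with columns `N`, `E`, `tau`
#' @export
pt_synth_tau <- function(spec) {
  stopifnot(inherits(spec, "pt_synth_spec"))
  with_private_seed(spec$seed, function() {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    grid <- expand.grid(N = spec$N_list, E = spec$E_list)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      med <- spec$c0 * grid$N[i]^spec$alpha_true * grid$E[i]^-spec$delta_true
      tau <- if (sdlog == 0) rep(med, spec$n_runs)
             else rlnorm(spec$n_runs, meanlog = log(med), sdlog = sdlog)
      data.frame(N = grid$N[i], E = grid$E[i], tau = tau)
    }))
  })
}

#' Synthetic translocation-coordinate trajectory
#'
#' A monotone-on-average integer series from 1 to N whose ensemble MSD
#' grows as `t^beta` at late times: the drift part is
#' `s = 1 + (N - 1) t~^(beta/2)` and a bounded zigzag perturbation mimics
#' the diffusive character of measured translocation coordinates. The final
#' value is always N.
#'
#' @param N chain length
#' @param beta_true late-time MSD exponent (> 0)
#' @param n_steps number of samples along the run
#' @param seed integer seed
#' @param noise zigzag amplitude in monomers (0 = deterministic drift)
#' @return list with `time` (in `[0, 1]`), `s`, `tau` (= 1), compatible
#'   with [pt_translocation_msd()]
#' @export
pt_synth_s_traj <- function(N, beta_true, n_steps = 100, seed = 1,
                            noise = 1.0) {
  stopifnot(beta_true > 0, N >= 2)
  with_private_seed(seed, function() {
    tt <- seq(0, 1, length.out = n_steps + 1)
    s <- 1 + (N - 1) * tt^(beta_true / 2)
    if (noise > 0) {
      eps <- runif(length(s), -noise, noise)
      eps[1] <- 0; eps[length(eps)] <- 0
      s <- pmin(pmax(round(s + eps), 1), N)
    }
    s[length(s)] <- N
    list(time = tt, s = s, tau = 1)
  })
}

#' Synthetic ion-condensation configuration with known ground truth
#'
#' A straight test chain along z plus exactly `n_condensed` ions placed
#' within the Bjerrum length of some monomer and `n_free` ions farther than
#' the Bjerrum length from every monomer, in a box large enough that no
#' minimum-image ambiguity arises.
#'
#' @param n_condensed,n_free ion counts
#' @param lambda_B Bjerrum length (condensation cutoff)
#' @param seed integer seed
#' @param N chain length of the test chain
#' @return a frame list (`pos`, `charge`, `species`, `n_monomer`, `box`,
#'   `z_lo`, `z_hi`) consumable by [pt_condensation()]
#' @export
pt_synth_condensation <- function(n_condensed, n_free, lambda_B = 3.0,
                                  seed = 1, N = 16) {
  stopifnot(n_condensed >= 0, n_free >= 0, N >= 2)
  with_private_seed(seed, function() {
    margin <- 4 * lambda_B + N
    box <- c(margin, margin, margin + N)
    x0 <- box[1] / 2; y0 <- box[2] / 2; z0 <- lambda_B + 2
    mono <- cbind(rep(x0, N), rep(y0, N), z0 + seq_len(N) - 1)
    cond <- matrix(numeric(0), 0, 3)
    if (n_condensed > 0)
      cond <- t(vapply(seq_len(n_condensed), function(i) {
        j <- sample.int(N, 1)
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        mono[j, ] + runif(1, 0.3 * lambda_B, 0.9 * lambda_B) * u
      }, numeric(3)))
    free <- matrix(numeric(0), 0, 3)
    if (n_free > 0)
      free <- t(vapply(seq_len(n_free), function(i) {
        for (try in seq_len(200)) {
          u <- rnorm(2); u <- u / sqrt(sum(u^2))
          rho <- runif(1, lambda_B + 0.5, 2 * lambda_B)
          cand <- c(x0 + rho * u[1], y0 + rho * u[2],
                    runif(1, 1, box[3] - 1))
          dmin <- sqrt(min(rowSums(sweep(mono, 2, cand)^2)))
          if (dmin > lambda_B + 0.2) return(cand)
        }
        stop("packing error: could not place a free ion")
      }, numeric(3)))
    # verify construction: condensed < lambda_B, free > lambda_B
    check <- function(p, want_in) {
      if (!nrow(p)) return(invisible())
      for (i in seq_len(nrow(p))) {
        dmin <- sqrt(min(rowSums(sweep(mono, 2, p[i, ])^2)))
        stopifnot((dmin < lambda_B) == want_in)
      }
    }
    check(cond, TRUE); check(free, FALSE)
    n_ion <- n_condensed + n_free
    list(pos = rbind(mono, cond, free),
         charge = c(rep(-1, N), rep(1, n_ion)),
         species = c(rep("monomer", N), rep("counterion", n_ion)),
         n_monomer = N, box = box, z_lo = -1, z_hi = 0)
  })
}
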