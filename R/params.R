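#' Force-field parameter bundle
#'
#' Collects the bead-spring / electrostatic force-field constants in reduced
#' units. The defaults are the production values used throughout:
#' bead-bead WCA diameter 1.0 and strength 1.2 kT, bead-wall WCA diameter
#' 1.5 and strength 2.5 kT, harmonic bond constant 600 kT/sigma^2 with
#' equilibrium length 1.0, Bjerrum length 3.0 sigma, friction 1.0 m/tau_u,
#' temperature 1.0.
#'
#' @param sigma_bb bead-bead Lennard-Jones diameter (sigma)
#' @param eps_bb bead-bead strength (kT)
#' @param sigma_bw bead-wall diameter (sigma)
#' @param eps_bw bead-wall strength (kT)
#' @param k_bond harmonic spring constant (kT/sigma^2)
#' @param r0 equilibrium bond length (sigma)
#' @param lambda_B Bjerrum length (sigma); distance at which two unit
#'   charges interact with energy kT
#' @param zeta friction coefficient (m/tau_u)
#' @param T temperature (kT = 1 in reduced units)
#' @param mass bead mass (uniform)
#' @return an object of class `pt_model_params`
#' @export
pt_model_params <- function(sigma_bb = 1.0, eps_bb = 1.2,
                            sigma_bw = 1.5, eps_bw = 2.5,
                            k_bond = 600.0, r0 = 1.0,
                            lambda_B = 3.0, zeta = 1.0, T = 1.0,
                            mass = 1.0) {
  p <- list(sigma_bb = sigma_bb, eps_bb = eps_bb,
            sigma_bw = sigma_bw, eps_bw = eps_bw,
            k_bond = k_bond, r0 = r0, lambda_B = lambda_B,
            zeta = zeta, T = T, mass = mass)
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  bad <- setdiff(bad, "zeta")              # zeta = 0 is the NVE limit
  if (!(is.numeric(p$zeta) && length(p$zeta) == 1L && p$zeta >= 0))
    bad <- c(bad, "zeta")
  if (length(bad))
    stop("model parameters must be strictly positive scalars; offending: ",
         paste(bad, collapse = ", "))
  structure(p, class = "pt_model_params")
}

#' Langevin integration parameters
#'
#' @param dt time step (tau_u); production values lie in 0.0001..0.005
#' @param seed integer RNG seed for the noise stream (one independent
#'   stream per run; derive per-run seeds from a master seed)
#' @param zeta friction (m/tau_u)
#' @param T temperature
#' @return an object of class `pt_langevin_params`
#' @export
pt_langevin_params <- function(dt = 0.005, seed = 1L, zeta = 1.0, T = 1.0) {
  if (!is.numeric(dt) || dt <= 0 || dt > 0.02)
    stop("dt must be a positive time step (production range 0.0001..0.005)")
  structure(list(dt = dt, seed = as.double(seed), zeta = zeta, T = T),
            class = "pt_langevin_params")
}

#' Default time step for a given field strength
#'
#' Stronger driving fields need smaller steps: 0.005 for E <= 1, 0.001 for
#' 1 < E <= 10, 0.0005 beyond. Any run may override this.
#'
#' @param E field strength (kT / (e sigma))
#' @return time step in tau_u
#' @export
pt_default_dt <- function(E) {
  stopifnot(is.numeric(E), all(E >= 0))
  ifelse(E <= 1, 0.005, ifelse(E <= 10, 0.001, 5e-4))
}

#' Ewald summation parameters from an accuracy target
#'
#' Chooses the splitting parameter alpha, the real-space cutoff and the
#' reciprocal-space extent so that the estimated relative RMS force error is
#' at or below `accuracy`. The real-space cutoff defaults to half the
#' smallest box edge (the minimum-image limit), `alpha = s / r_cut` and the
#' per-dimension mode counts follow from the reciprocal cutoff
#' `k_max = 2 alpha s`, with `s = sqrt(-log(accuracy))`.
#'
#' @param box box edge lengths, length-3
#' @param accuracy relative RMS force error target (default 1e-3)
#' @param r_cut optional real-space cutoff override (must be <= min(box)/2)
#' @param alpha optional splitting-parameter override (1/sigma)
#' @return an object of class `pt_ewald_params` with fields `accuracy`,
#'   `alpha`, `r_cut`, `n_k` (real-valued semi-axes of the included
#'   reciprocal-mode ellipsoid)
#' @export
pt_ewald_params <- function(box, accuracy = 1e-3, r_cut = NULL, alpha = NULL) {
  stopifnot(length(box) == 3, all(box > 0))
  if (!is.numeric(accuracy) || accuracy <= 0 || accuracy >= 1)
    stop("accuracy must be in (0, 1)")
  s <- sqrt(-log(accuracy))
  if (is.null(r_cut)) r_cut <- min(box) / 2
  if (r_cut > min(box) / 2 + 1e-9)
    stop("r_cut = ", r_cut, " exceeds half the smallest box edge (",
         min(box) / 2, "): inconsistent Ewald parameterization")
  if (is.null(alpha)) alpha <- s / r_cut
  if (alpha <= 0) stop("alpha must be positive")
  n_k <- alpha * s * box / pi    # k_max L / (2 pi) with k_max = 2 alpha s
  structure(list(accuracy = accuracy, alpha = alpha, r_cut = r_cut,
                 n_k = n_k, s = s),
            class = "pt_ewald_params")
}

#' Run configuration for one translocation experiment
#'
#' The default ion content is the production condition: one neutralizing
#' counterion per monomer plus 256 salt cations and 256 salt anions.
#'
#' @param N chain length (number of monomers)
#' @param E driving field strength inside the pore (kT / (e sigma))
#' @param n_salt_cations,n_salt_anions added salt ion counts
#' @param equilibration_steps steps of tethered zero-field equilibration
#' @param max_steps cap on driven steps before a run is declared incomplete
#' @param seed master seed for the run
#' @param frame_every steps between stored trajectory frames
#' @return an object of class `pt_run_config`
#' @export
pt_run_config <- function(N, E, n_salt_cations = 256L, n_salt_anions = 256L,
                          equilibration_steps = 20000L, max_steps = 2000000L,
                          seed = 1L, frame_every = 200L) {
  if (!is.numeric(N) || N < 2 || N != round(N))
    stop("N must be an integer chain length >= 2")
  if (!is.numeric(E) || E < 0)
    stop("E must be a nonnegative field strength")
  if (n_salt_cations < 0 || n_salt_anions < 0)
    stop("salt counts must be nonnegative")
  if (n_salt_cations != n_salt_anions)
    warning("unequal salt counts break salt neutrality; counterions still ",
            "neutralize the chain but the total system must remain neutral")
  structure(list(N = as.integer(N), E = E,
                 n_salt_cations = as.integer(n_salt_cations),
                 n_salt_anions = as.integer(n_salt_anions),
                 equilibration_steps = as.integer(equilibration_steps),
                 max_steps = as.integer(max_steps),
                 seed = as.double(seed),
                 frame_every = as.integer(frame_every)),
            class = "pt_run_config")
}
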