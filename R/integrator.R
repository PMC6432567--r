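#' Advance the system by Langevin dynamics
#'
#' Integrates `m r'' = -zeta r' - grad U + Z e E(r) + eta` with the
#' Gronbech-Jensen/Farago discretization (a Verlet-family scheme that gives
#' correct configurational sampling over the whole production time-step
#' range and reduces exactly to velocity Verlet at `zeta = 0`). The noise
#' obeys the fluctuation-dissipation relation
#' `<eta_i(t) . eta_j(t')> = 6 kT zeta delta_ij delta(t - t')`. The
#' trajectory is deterministic given (state, seed) on one platform.
#'
#' @param state a [pt_state()]
#' @param topo a [pt_bond_topology()] or NULL
#' @param geom a [pt_geometry()]
#' @param params a [pt_model_params()]
#' @param lp a [pt_langevin_params()] (time step, seed, friction,
#'   temperature); `lp$zeta`/`lp$T` override the model bundle
#' @param n_steps number of steps
#' @param E in-pore field strength (0 = no field)
#' @param frame_every steps between stored frames
#' @param tether 1-based bead index held immobile (NULL = none)
#' @param barrier enable the one-way exit barrier on monomer 1
#' @param detect_first_passage stop when the last monomer leaves the pore
#'   exit (all monomers past `z_hi`); the crossing time is interpolated
#'   linearly within the step
#' @param ewald a [pt_ewald_params()]; default from the geometry box
#' @param record_energy also record total energy at each stored frame
#' @return list with the advanced `state`, a `traj` object of class
#'   `pt_traj` (frames, times, instantaneous kinetic temperature, species,
#'   charges, geometry extract), `tau` (first-passage time or NA),
#'   `completed`, and `steps_done`
#' @export
pt_run_dynamics <- function(state, topo = NULL, geom, params = pt_model_params(),
                            lp = pt_langevin_params(), n_steps,
                            E = 0, frame_every = 100L, tether = NULL,
                            barrier = FALSE, detect_first_passage = FALSE,
                            ewald = NULL, record_energy = FALSE) {
  stopifnot(inherits(state, "pt_state"), inherits(geom, "pt_geometry"))
  do_coulomb <- any(state$charge != 0)
  if (do_coulomb && abs(sum(state$charge)) > 1e-9)
    stop("electroneutrality violated: total charge = ", sum(state$charge))
  if (is.null(ewald)) ewald <- pt_ewald_params(geom$box)
  if (is.null(topo)) { bf <- integer(0); bt <- integer(0) }
  else { bf <- topo$bonds[, 1] - 1L; bt <- topo$bonds[, 2] - 1L }
  pars <- unclass(params)
  pars$zeta <- lp$zeta
  pars$T <- lp$T
  out <- .run_dynamics_cpp(state$positions, state$velocities, state$charge,
                           bf, bt, geom$wall, .geom_cpp(geom), pars,
                           list(alpha = ewald$alpha, r_cut = ewald$r_cut,
                                n_k = ewald$n_k),
                           E, state$n_monomer,
                           as.integer(n_steps), lp$dt, lp$seed,
                           as.integer(frame_every),
                           if (is.null(tether)) -1L else as.integer(tether) - 1L,
                           isTRUE(barrier), isTRUE(detect_first_passage),
                           do_coulomb, isTRUE(record_energy))
  new_state <- pt_state(out$pos, out$vel, state$charge, state$species,
                        check_neutral = FALSE)
  traj <- structure(list(frames = out$frames, time = out$frame_time,
                         temp = out$frame_temp,
                         energy = if (record_energy) out$frame_energy else NULL,
                         species = state$species, charge = state$charge,
                         n_monomer = state$n_monomer,
                         box = geom$box, z_lo = geom$z_lo, z_hi = geom$z_hi,
                         dt = lp$dt, seed = lp$seed,
                         tau = out$tau),
                    class = "pt_traj")
  list(state = new_state, traj = traj, tau = out$tau,
       completed = out$completed, steps_done = out$steps_done)
}

#' Instantaneous kinetic temperature
#'
#' `T_kin = 2 E_kin / (3 n k_B)` over the mobile beads.
#'
#' @param state a [pt_state()], or a velocity matrix
#' @param mass bead mass
#' @return temperature in reduced units
#' @export
pt_kinetic_temperature <- function(state, mass = 1.0) {
  v <- if (inherits(state, "pt_state")) state$velocities else as.matrix(state)
  n <- nrow(v)
  if (n < 1) stop("kinetic temperature needs at least one mobile bead")
  ekin <- 0.5 * mass * sum(v^2)
  2 * ekin / (3 * n)
}
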