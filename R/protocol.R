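#' Derive independent sub-seeds from a master seed
#'
#' One RNG stream per run, keyed by (master seed, run index); values stay
#' below 2^31.
#'
#' @param master master seed (integer)
#' @param k run index (integer or vector)
#' @return integer-valued seeds
#' @export
pt_seed_stream <- function(master, k) {
  (as.double(master) %% 1048573) * 104729 + as.double(k) * 7919 + 1
}

# run fn with a private R RNG stream; restores the caller's stream
with_private_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483646) + 1L)
  fn()
}

# calibrate the direction-mixing amplitude s so that the persistent walk
# d' = normalize(d + s u), u uniform on the sphere, has <cos theta> = target
.persistence_mix <- function(target) {
  target <- min(max(target, 0.01), 0.985)
  mean_cos <- function(s) {
    f <- function(x) (1 + s * x) / sqrt(1 + 2 * s * x + s * s)
    integrate(f, -1, 1)$value / 2
  }
  uniroot(function(s) mean_cos(s) - target, c(1e-3, 50))$root
}

#' Assemble the initial threaded system
#'
#' Places monomer 1 on the pore axis just at the trans-side opening, threads
#' the next monomers through the channel, and lays the rest of the chain
#' into the cis compartment as a self-avoiding persistent walk whose
#' persistence length is set to the Debye screening length computed from
#' the free-ion content (the physically expected stiffness scale of the
#' partially screened chain, and a starting coil that short tethered
#' equilibration can relax locally). Counterions and salt ions are placed
#' uniformly at random in the two compartments, excluding the wall slab and
#' channel interior, with a minimum pair separation of 0.85 sigma.
#'
#' @param cfg a [pt_run_config()]
#' @param geom a [pt_geometry()]
#' @param params a [pt_model_params()]
#' @return a [pt_state()]: N monomers (valence -1), N counterions (+1),
#'   then the salt cations (+1) and anions (-1); total charge zero
#' @export
pt_init_system <- function(cfg, geom, params = pt_model_params()) {
  stopifnot(inherits(cfg, "pt_run_config"), inherits(geom, "pt_geometry"))
  with_private_seed(cfg$seed, function() .init_system_impl(cfg, geom, params))
}

.init_system_impl <- function(cfg, geom, params) {
  N <- cfg$N
  box <- geom$box
  clearance <- 2^(1 / 6) * params$sigma_bw + 0.02  # stay out of wall range
  z_top_margin <- 2.0
  cis_zmax <- geom$z_lo - clearance
  if (cis_zmax < 3) stop("box too small for the wall clearance")

  mind <- 0.85
  pos <- matrix(NA_real_, N, 3)
  pos[1, ] <- c(geom$axis_x, geom$axis_y, geom$z_hi + 0.25)
  n_axis <- min(N, ceiling(0.25 + geom$pore_length + clearance) + 1)
  for (i in seq_len(n_axis)[-1])
    pos[i, ] <- c(geom$axis_x, geom$axis_y, pos[1, 3] - (i - 1) * params$r0)

  if (N > n_axis) {
    # chain stiffness for the starting coil: intra-chain repulsion is
    # unscreened below the Debye length of the free-ion cloud, so the walk
    # persistence is set to that screening length (the OSF estimate with
    # the Manning-reduced charge is known to understate the stiffness of
    # flexible, strongly charged chains)
    n_ion <- N + cfg$n_salt_cations + cfg$n_salt_anions
    c_ion <- n_ion / prod(box)
    l_p <- max(params$r0,
               1 / sqrt(4 * pi * params$lambda_B * max(c_ion, 1e-12)))
    mix <- .persistence_mix(exp(-params$r0 / l_p))
    dirv <- c(0, 0, -1)
    i <- n_axis + 1L
    backtracks <- 0L
    while (i <= N) {
      placed <- FALSE
      for (try in seq_len(60)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        d2 <- dirv + mix * u; d2 <- d2 / sqrt(sum(d2^2))
        cand <- pos[i - 1, ] + params$r0 * d2
        if (cand[3] > cis_zmax || cand[3] < z_top_margin) {
          # specular reflection off the slab boundaries keeps the walk's
          # persistence instead of scrambling it
          d2[3] <- -d2[3]
          cand <- pos[i - 1, ] + params$r0 * d2
          if (cand[3] > cis_zmax || cand[3] < z_top_margin) next
        }
        prev <- pos[seq_len(i - 2), , drop = FALSE]  # skip bonded neighbour
        if (nrow(prev)) {
          dd <- abs(sweep(prev, 2, cand))
          dd[, 1] <- pmin(dd[, 1], box[1] - dd[, 1])
          dd[, 2] <- pmin(dd[, 2], box[2] - dd[, 2])
          dd[, 3] <- pmin(dd[, 3], box[3] - dd[, 3])
          if (min(rowSums(dd^2)) < mind^2) next
        }
        pos[i, ] <- cand
        dirv <- d2
        placed <- TRUE
        break
      }
      if (placed) { i <- i + 1L } else {
        backtracks <- backtracks + 1L
        if (backtracks > 50 * N)
          stop("packing error: could not grow the initial chain (N = ", N, ")")
        i <- max(n_axis + 1L, i - 1L)
        dirv <- dirv + 0.5 * rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      }
    }
  }

  # counterions: each is dissociated from a monomer, so it starts in a
  # shell a few bead diameters from the chain (the condensed-cloud scale);
  # salt ions: uniform over both compartments, away from the wall slab
  n_ions <- N + cfg$n_salt_cations + cfg$n_salt_anions
  all_pos <- pos
  ion_pos <- matrix(NA_real_, n_ions, 3)
  zlo_ex <- geom$z_lo - clearance
  zhi_ex <- geom$z_hi + clearance
  ok_z <- function(z) z > 0.5 && z < box[3] - 0.5 && !(z > zlo_ex && z < zhi_ex)
  for (j in seq_len(n_ions)) {
    ok <- FALSE
    for (try in seq_len(400)) {
      if (j <= N) {                     # counterion: dissociation shell
        anchor <- pos[sample.int(N, 1), ]
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- anchor + runif(1, 1.0, 4.0) * u
        cand[1] <- cand[1] %% box[1]
        cand[2] <- cand[2] %% box[2]
        if (!ok_z(cand[3])) next
      } else {                          # salt: uniform in the compartments
        zcand <- runif(1, 0.5, box[3] - 0.5)
        if (!ok_z(zcand)) next
        cand <- c(runif(1, 0, box[1]), runif(1, 0, box[2]), zcand)
      }
      dd <- abs(sweep(all_pos, 2, cand))
      dd[, 1] <- pmin(dd[, 1], box[1] - dd[, 1])
      dd[, 2] <- pmin(dd[, 2], box[2] - dd[, 2])
      dd[, 3] <- pmin(dd[, 3], box[3] - dd[, 3])
      if (min(rowSums(dd^2)) < mind^2) next
      ion_pos[j, ] <- cand
      all_pos <- rbind(all_pos, cand)
      ok <- TRUE
      break
    }
    if (!ok) stop("packing error: could not place ion ", j)
  }

  species <- c(rep("monomer", N), rep("counterion", N),
               rep("cation", cfg$n_salt_cations),
               rep("anion", cfg$n_salt_anions))
  charge <- c(rep(-1, N), rep(1, N),
              rep(1, cfg$n_salt_cations), rep(-1, cfg$n_salt_anions))
  positions <- rbind(pos, ion_pos)
  # wrap x,y (the walk may have spread past the periodic edges)
  positions[, 1] <- positions[, 1] %% box[1]
  positions[, 2] <- positions[, 2] %% box[2]
  positions[, 3] <- positions[, 3] %% box[3]
  vel <- matrix(rnorm(nrow(positions) * 3, sd = sqrt(params$T / params$mass)),
                ncol = 3)
  pt_state(positions, vel, charge, species,
           check_neutral = (sum(charge) == 0))
}

#' Tethered zero-field equilibration
#'
#' Runs Langevin dynamics with the driving field off and monomer 1 held
#' immobile at its threaded position, then reports the equilibrium-state
#' observables used as the normalized-time t~ = 0 anchors: mean bond
#' length, kinetic temperature, and the cis-side radius of gyration series.
#'
#' Equilibrium ensembles are independent of the Langevin friction, so the
#' leading `relax_fraction` of the steps run at the reduced friction
#' `relax_zeta` (chosen near the critical damping of the slowest chain
#' mode), which accelerates the conformational relaxation of long chains by
#' several-fold without changing any static observable; the remaining steps
#' run at the production friction and provide every reported frame. A
#' split-half comparison of the R_g,I series flags non-convergence; a
#' kinetic temperature more than 5% off target raises a warning.
#'
#' @param state a [pt_state()] from [pt_init_system()]
#' @param cfg a [pt_run_config()]
#' @param geom,params geometry and force field
#' @param dt time step (zero field, so the coarse default applies)
#' @param n_steps override `cfg$equilibration_steps`
#' @param frame_every frame cadence
#' @param burn_frames leading production-stage frames excluded from the
#'   reported averages
#' @param relax_zeta friction of the accelerated relaxation stage
#'   (m/tau_u); set equal to `params$zeta` to disable the stage
#' @param relax_fraction fraction of `n_steps` spent in the relaxation
#'   stage
#' @return list with the relaxed `state`, the production-stage `traj`, and
#'   `equil` (mean_bond, kinetic_T, rg_I series, converged flag)
#' @export
pt_equilibrate <- function(state, cfg, geom, params = pt_model_params(),
                           dt = 0.005, n_steps = NULL, frame_every = NULL,
                           burn_frames = NULL, relax_zeta = 0.15,
                           relax_fraction = 0.5) {
  if (is.null(n_steps)) n_steps <- cfg$equilibration_steps
  if (is.null(frame_every)) frame_every <- cfg$frame_every
  topo <- pt_bond_topology(cfg$N)
  n1 <- if (relax_zeta < params$zeta) floor(n_steps * relax_fraction) else 0L
  if (n1 > 0) {
    lp1 <- pt_langevin_params(dt = dt, seed = pt_seed_stream(cfg$seed, 1),
                              zeta = relax_zeta, T = params$T)
    state <- pt_run_dynamics(state, topo, geom, params, lp1, n1,
                             E = 0, frame_every = n1, tether = 1L)$state
  }
  lp <- pt_langevin_params(dt = dt, seed = pt_seed_stream(cfg$seed, 51),
                           zeta = params$zeta, T = params$T)
  out <- pt_run_dynamics(state, topo, geom, params, lp, n_steps - n1,
                         E = 0, frame_every = frame_every, tether = 1L)
  traj <- out$traj
  nf <- length(traj$time)
  if (is.null(burn_frames)) burn_frames <- floor(nf / 2)
  keep <- seq.int(min(burn_frames + 1, nf), nf)

  bl <- vapply(keep, function(f) mean(.bond_lengths(traj, f)), numeric(1))
  rgI <- vapply(seq_len(nf), function(f) {
    r <- pt_frame_rg(traj, f)
    r[["I"]]
  }, numeric(1))
  Tkin <- mean(traj$temp[keep])
  if (is.finite(Tkin) && abs(Tkin - params$T) > 0.05 * params$T)
    warning("equilibration-quality warning: kinetic temperature ",
            signif(Tkin, 4), " is > 5% off target ", params$T)
  h1 <- rgI[seq_len(floor(nf / 2))]
  h2 <- rgI[seq.int(floor(nf / 2) + 1, nf)]
  converged <- is.finite(mean(h1, na.rm = TRUE)) &&
    abs(mean(h1, na.rm = TRUE) - mean(h2, na.rm = TRUE)) <=
      2 * stats::sd(rgI, na.rm = TRUE)
  list(state = out$state, traj = traj,
       equil = list(mean_bond = mean(bl), kinetic_T = Tkin,
                    rg_I = rgI, converged = converged))
}

# bond lengths (minimum image) of the chain at frame f
.bond_lengths <- function(traj, f) {
  N <- traj$n_monomer
  p <- t(traj$frames[, seq_len(N), f])
  d <- abs(p[-1, , drop = FALSE] - p[-N, , drop = FALSE])
  for (k in 1:3) d[, k] <- pmin(d[, k], traj$box[k] - d[, k])
  sqrt(rowSums(d^2))
}

#' Run one driven translocation to first passage
#'
#' Switches the field on, releases the tether, and integrates until the
#' last monomer leaves the pore exit (all monomers beyond the exit plane)
#' or `cfg$max_steps` is reached. The one-way barrier (a purely repulsive
#' LJ plane at the exit, visible only to monomer 1 and armed once monomer 1
#' has cleared its range) prevents back-threading, so completed runs are
#' guaranteed forward translocations. The first-passage time is
#' interpolated linearly within the crossing step.
#'
#' @param state equilibrated [pt_state()]
#' @param cfg a [pt_run_config()]
#' @param geom,params geometry and force field
#' @param dt time step; default [pt_default_dt()] of the field strength
#' @param frame_every frame cadence
#' @return object of class `pt_result`: `tau` (tau_u; NA if incomplete),
#'   `completed`, `n_frames`, `seed`, `dt`, and the `traj`
#' @export
pt_run_translocation <- function(state, cfg, geom, params = pt_model_params(),
                                 dt = NULL, frame_every = NULL) {
  if (is.null(dt)) dt <- pt_default_dt(cfg$E)
  if (is.null(frame_every)) frame_every <- cfg$frame_every
  lp <- pt_langevin_params(dt = dt, seed = pt_seed_stream(cfg$seed, 2),
                           zeta = params$zeta, T = params$T)
  topo <- pt_bond_topology(cfg$N)
  out <- pt_run_dynamics(state, topo, geom, params, lp, cfg$max_steps,
                         E = cfg$E, frame_every = frame_every,
                         barrier = TRUE, detect_first_passage = TRUE)
  if (!out$completed)
    warning("run did not complete within max_steps = ", cfg$max_steps)
  out$traj$tau <- out$tau
  structure(list(tau = out$tau, completed = out$completed,
                 n_frames = length(out$traj$time),
                 seed = cfg$seed, dt = dt, traj = out$traj,
                 state = out$state),
            class = "pt_result")
}
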