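#' Purely repulsive (WCA) pair potential
#'
#' Lennard-Jones potential truncated at its minimum `2^(1/6) sigma` and
#' shifted so that energy and radial force both vanish continuously at the
#' cutoff:
#' `U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6 + 1/4)` for `r <= 2^(1/6) sigma`,
#' zero beyond. Used bead-bead (`sigma = 1, eps = 1.2`) and bead-wall
#' (`sigma = 1.5, eps = 2.5`).
#'
#' @param r separation distance(s), > 0
#' @param sigma LJ diameter
#' @param eps LJ strength (kT)
#' @return list with `energy` and `force` (radial force, -dU/dr; positive =
#'   repulsive), each the length of `r`
#' @export
pt_wca <- function(r, sigma = 1.0, eps = 1.2) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("pt_wca: separation r must be strictly positive")
  rc <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  u <- ifelse(r <= rc, 4 * eps * (s6^2 - s6 + 0.25), 0)
  f <- ifelse(r <= rc, 24 * eps * (2 * s6^2 - s6) / r, 0)
  list(energy = u, force = f)
}

#' Harmonic bond potential
#'
#' `U(r) = (k/2) (r - r0)^2`, radial force `-k (r - r0)` (positive =
#' repulsive when compressed).
#'
#' @param r bond length(s), >= 0
#' @param params a [pt_model_params()] bundle supplying `k_bond` and `r0`
#' @return list with `energy` and `force`
#' @export
pt_bond <- function(r, params = pt_model_params()) {
  if (any(r < 0)) stop("pt_bond: bond length must be nonnegative")
  k <- params$k_bond
  r0 <- params$r0
  list(energy = 0.5 * k * (r - r0)^2, force = -k * (r - r0))
}

#' Bare (non-periodic) Coulomb pair energy
#'
#' `U(r) = kT lambda_B Zi Zj / r`: the reference form of the electrostatic
#' interaction, with the Bjerrum length setting the strength. The periodic
#' production sum is in [pt_ewald()]; this form anchors its unit tests and
#' the direct-sum oracle.
#'
#' @param r separation(s), > 0
#' @param zi,zj charge valences
#' @param lambda_B Bjerrum length (sigma)
#' @return energy in kT
#' @export
pt_coulomb <- function(r, zi, zj, lambda_B = 3.0) {
  if (any(r <= 0)) stop("pt_coulomb: separation r must be strictly positive")
  lambda_B * zi * zj / r
}

#' System microstate
#'
#' Positions, velocities, charges and species of all mobile beads. Monomers
#' must occupy the leading contiguous indices in chain order; the wall is
#' held separately in the geometry (immobile beads receive no updates and
#' carry no charge).
#'
#' @param positions n x 3 matrix (sigma)
#' @param velocities n x 3 matrix (sigma/tau_u); defaults to zero
#' @param charge integer valences per bead (-1 monomer, +1 counterion or
#'   cation, -1 anion, 0 allowed for test systems)
#' @param species character per bead: "monomer", "counterion", "cation",
#'   "anion" (or "neutral" in test systems)
#' @param check_neutral error if the total charge is nonzero (default TRUE;
#'   disable only for partial test systems that never reach the Ewald sum)
#' @return an object of class `pt_state`
#' @export
pt_state <- function(positions, velocities = NULL, charge, species,
                     check_neutral = TRUE) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, length(charge) == n, length(species) == n)
  if (any(!is.finite(positions))) stop("positions must be finite")
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  mono <- which(species == "monomer")
  if (length(mono) && !identical(mono, seq_along(mono)))
    stop("monomers must occupy the leading contiguous indices in chain order")
  if (check_neutral && sum(charge) != 0)
    stop("electroneutrality violated: total charge = ", sum(charge))
  structure(list(positions = positions, velocities = as.matrix(velocities),
                 charge = as.numeric(charge), species = as.character(species),
                 n_monomer = length(mono)),
            class = "pt_state")
}

#' Linear bond topology of the chain
#'
#' @param N chain length
#' @return object of class `pt_bond_topology`: an (N-1) x 2 matrix of
#'   1-based bead index pairs forming a single unbranched path
#' @export
pt_bond_topology <- function(N) {
  stopifnot(N >= 2)
  structure(list(bonds = cbind(seq_len(N - 1), seq_len(N - 1) + 1L), N = N),
            class = "pt_bond_topology")
}

#' Total conservative force on every mobile bead
#'
#' Assembles bead-bead WCA (bonded neighbours excluded), bead-wall WCA,
#' harmonic bonds, periodic Coulomb (Ewald) over all charged beads, the
#' in-pore driving field `Z_i e E_vec` acting on every charged bead inside
#' the cylindrical channel, and (optionally) the one-way exit barrier.
#' Internal forces (everything except wall, field and barrier) sum to zero.
#'
#' @param state a [pt_state()]
#' @param topo a [pt_bond_topology()] or NULL for an unbonded system
#' @param geom a [pt_geometry()]
#' @param params a [pt_model_params()]
#' @param E field strength inside the pore (kT/(e sigma)); the field is a
#'   step function: exactly `-E zhat` inside the channel volume, zero outside
#' @param ewald a [pt_ewald_params()]; default derived from the geometry box
#'   at accuracy 1e-3
#' @param barrier_armed whether the one-way exit-plane barrier acts on
#'   monomer 1
#' @return list with `forces` (n x 3), total potential `energy`, and the
#'   per-term energy components
#' @export
pt_forces <- function(state, topo = NULL, geom, params = pt_model_params(),
                      E = 0, ewald = NULL, barrier_armed = FALSE) {
  stopifnot(inherits(state, "pt_state"), inherits(geom, "pt_geometry"))
  do_coulomb <- any(state$charge != 0)
  if (do_coulomb && abs(sum(state$charge)) > 1e-9)
    stop("electroneutrality violated: total charge = ", sum(state$charge))
  if (is.null(ewald)) ewald <- pt_ewald_params(geom$box)
  if (is.null(topo)) {
    bf <- integer(0); bt <- integer(0)
  } else {
    bf <- topo$bonds[, 1] - 1L; bt <- topo$bonds[, 2] - 1L
  }
  .forces_cpp(state$positions, state$charge, bf, bt,
              geom$wall, .geom_cpp(geom), unclass(params),
              list(alpha = ewald$alpha, r_cut = ewald$r_cut, n_k = ewald$n_k),
              E, state$n_monomer, do_coulomb, barrier_armed)
}
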