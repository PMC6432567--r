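#' Periodic Coulomb energy and forces by smooth Ewald summation
#'
#' Classical Ewald decomposition (real + reciprocal + self term, tin-foil
#' boundary by default) of the Coulomb sum `kT lambda_B Zi Zj / r` over the
#' fully periodic box, with parameters chosen by [pt_ewald_params()] so that
#' the relative RMS force error is at or below the accuracy target (default
#' 1e-3). The result is independent, to that tolerance, of the split
#' between real and reciprocal space.
#'
#' @param positions n x 3 matrix (sigma)
#' @param charge valences (must sum to zero)
#' @param box periodic box edges
#' @param ewald a [pt_ewald_params()]; default from `box` at 1e-3
#' @param lambda_B Bjerrum length
#' @param dipole_correction add the vacuum (epsilon' = 1) surface-dipole
#'   term; use when comparing against the spherically ordered direct lattice
#'   sum, never in dynamics
#' @return list with `energy` (kT), `forces` (n x 3), and the energy parts
#' @export
pt_ewald <- function(positions, charge, box, ewald = NULL, lambda_B = 3.0,
                     dipole_correction = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(charge),
            length(box) == 3, all(box > 0))
  if (abs(sum(charge)) > 1e-9)
    stop("Ewald requires a charge-neutral system (net charge = ",
         sum(charge), ")")
  if (is.null(ewald)) ewald <- pt_ewald_params(box)
  .ewald_cpp(positions, as.numeric(charge), as.numeric(box),
             ewald$alpha, ewald$r_cut, ewald$n_k, lambda_B,
             dipole_correction)
}

#' Direct lattice-sum oracle for the periodic Coulomb energy
#'
#' Real-space sum of the bare Coulomb form over all periodic images with
#' image indices `|n| <= n_images`, accumulated in spherical shells to
#' mitigate the conditional convergence of the lattice sum; the returned
#' energy averages the last two shell partial sums (which damps the
#' leading oscillation). Converges to the vacuum (epsilon' = 1) boundary
#' condition, so compare against [pt_ewald()] with
#' `dipole_correction = TRUE`. O(n^2 images^3): intended for test systems
#' of at most a few dozen charges.
#'
#' @param positions n x 3 matrix (use unwrapped coordinates)
#' @param charge valences
#' @param box box edges
#' @param n_images maximum image index per dimension
#' @param lambda_B Bjerrum length
#' @param partial if TRUE return the full vector of spherical partial sums
#'   (index s = 0..n_images) instead of the converged estimate
#' @return energy in kT, or the partial-sum vector
#' @export
pt_direct_sum <- function(positions, charge, box, n_images = 8,
                          lambda_B = 3.0, partial = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(charge))
  if (nrow(positions) > 64)
    stop("direct-sum oracle is O(n^2 images^3); use <= 64 charges")
  ps <- .direct_sum_cpp(positions, as.numeric(charge), as.numeric(box),
                        as.integer(n_images), lambda_B)
  if (partial) return(ps)
  n <- length(ps)
  if (n >= 2) mean(ps[(n - 1):n]) else ps[n]
}
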