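# Shared builders for small test systems. Everything is generated in code;
# no stored fixtures.

# small commensurate geometry: 16 x 19-row cross-section, short box
small_geom <- function(Lz = 60, layers = 4L, pore_radius = 2.25) {
  pt_geometry(box = c(16, 19 * sqrt(3) / 2, Lz), pore_radius = pore_radius,
              pore_length = 4.5, layers = layers)
}

# open box with no wall beads (degenerate punch): free-space dynamics
open_geom <- function(box = c(12, 12.99, 40)) {
  pt_geometry(box = box, layers = 1L, pore_radius = sum(box))
}

# random neutral charge configuration in a cubic box
random_charges <- function(n, L, seed) {
  set.seed(seed)
  list(pos = matrix(runif(n * 3, 0, L), n, 3),
       q = rep(c(1, -1), n / 2)[sample(n)],
       box = c(L, L, L))
}

# neutral charged gas state in an open box (ions only)
ion_gas <- function(n, geom, seed = 1) {
  set.seed(seed)
  lo <- c(1, 1, 1)
  hi <- geom$box - 1
  pos <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  q <- rep(c(1, -1), n / 2)
  pt_state(pos, charge = q,
           species = ifelse(q > 0, "cation", "anion"))
}

# minimal hand-built trajectory object
fake_traj <- function(frames, time, n_monomer, charge = NULL,
                      species = NULL, box = c(48, 49.36, 200),
                      z_lo = 97.75, z_hi = 102.25, tau = NULL) {
  n <- dim(frames)[2]
  if (is.null(charge)) charge <- c(rep(-1, n_monomer),
                                   rep(1, n - n_monomer))
  if (is.null(species)) species <- c(rep("monomer", n_monomer),
                                     rep("counterion", n - n_monomer))
  structure(list(frames = frames, time = time, temp = rep(1, length(time)),
                 species = species, charge = charge, n_monomer = n_monomer,
                 box = box, z_lo = z_lo, z_hi = z_hi, dt = 0.005, seed = 1,
                 tau = tau),
            class = "pt_traj")
}

# O(n^2) scalar-loop condensation oracle, independent of the vectorized path
condensation_oracle <- function(frame, lambda_B = 3) {
  N <- frame$n_monomer
  counts <- c(plus = 0, minus = 0)
  for (i in seq_len(nrow(frame$pos))) {
    if (i <= N || frame$charge[i] == 0) next
    dmin <- Inf
    for (j in seq_len(N)) {
      d <- abs(frame$pos[i, ] - frame$pos[j, ])
      d <- pmin(d, frame$box - d)
      dmin <- min(dmin, sqrt(sum(d^2)))
    }
    if (dmin < lambda_B) {
      k <- if (frame$charge[i] > 0) "plus" else "minus"
      counts[k] <- counts[k] + 1
    }
  }
  counts
}
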