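#' Membrane wall and pore geometry
#'
#' Builds the immobile membrane: `layers` planes of beads on a triangular
#' (hexagonal-packing) lattice spanning the full x-y cross-section, centered
#' at mid-z of the box, with a cylindrical pore of radius `pore_radius`
#' punched through along z. The lattice constant is 1.0 sigma; the box x and
#' y edges must be commensurate with it (the default 48.0 x 49.36 cross
#' section holds 48 columns x 57 rows per layer). Layers are spaced
#' `pore_length / (layers - 1)` apart so the wall slab spans the pore
#' length; buried interior-layer beads that no mobile bead can reach are
#' removed.
#'
#' Region convention: the driving field inside the channel is
#' `E_vec = -E zhat`, so the negatively charged chain is driven toward +z.
#' The cis compartment (region I) is the low-z side, the pore interval
#' (region II) is `z_lo <= z <= z_hi` (closed on both ends), and the trans
#' compartment (region III) is the high-z side.
#'
#' @param box box edges (sigma); default `c(48, 49.36, 200)`
#' @param pore_radius pore radius (sigma)
#' @param pore_length pore length along z (sigma)
#' @param layers number of wall layers (>= 1)
#' @param lattice_a lattice constant (sigma)
#' @param interaction_cutoff bead-wall interaction range used to decide
#'   which interior beads are buried (default `2^(1/6) * 1.5`)
#' @return object of class `pt_geometry` with the wall coordinates, pore
#'   interval `z_lo`/`z_hi` (entrance and exit planes), pore axis, and box
#' @export
pt_geometry <- function(box = c(48.0, 49.36, 200.0),
                        pore_radius = 2.25, pore_length = 4.5,
                        layers = 4L, lattice_a = 1.0,
                        interaction_cutoff = 2^(1 / 6) * 1.5) {
  stopifnot(length(box) == 3, all(box > 0), layers >= 1, pore_radius >= 0)
  a <- lattice_a
  ncols <- round(box[1] / a)
  dy0 <- a * sqrt(3) / 2
  nrows <- round(box[2] / dy0)
  if (ncols < 1 || nrows < 1 ||
      abs(ncols * a - box[1]) > 0.05 * a ||
      abs(nrows * dy0 - box[2]) > 0.05 * box[2] / nrows * 5)
    stop("box x-y cross-section is not commensurate with a triangular ",
         "lattice of constant ", a)
  dy <- box[2] / nrows                      # exact periodic fit
  zc <- box[3] / 2
  if (layers > 1) {
    dzl <- pore_length / (layers - 1)
    zlayers <- zc + (seq_len(layers) - (layers + 1) / 2) * dzl
  } else {
    zlayers <- zc
  }
  z_lo <- zc - pore_length / 2
  z_hi <- zc + pore_length / 2
  cx <- box[1] / 2
  cy <- box[2] / 2

  ix <- rep(seq_len(ncols) - 1L, times = nrows)
  iy <- rep(seq_len(nrows) - 1L, each = ncols)
  x <- ix * a + (iy %% 2L) * a / 2
  y <- iy * dy
  rho <- sqrt(pmin(abs(x - cx), box[1] - abs(x - cx))^2 +
              pmin(abs(y - cy), box[2] - abs(y - cy))^2)
  keep_punch <- rho >= pore_radius          # the punch: no center within R
  interior <- if (layers > 2) seq(2L, layers - 1L) else integer(0)
  wall <- do.call(rbind, lapply(seq_len(layers), function(l) {
    keep <- keep_punch
    if (l %in% interior) {
      # buried beads of inner layers are unreachable: keep only the ring
      # that lines the channel surface
      keep <- keep & (rho <= pore_radius + interaction_cutoff + 0.5)
    }
    if (!any(keep)) return(NULL)
    cbind(x[keep], y[keep], rep(zlayers[l], sum(keep)))
  }))
  if (is.null(wall)) wall <- matrix(numeric(0), 0, 3)
  structure(list(box = box, wall = wall,
                 pore_radius = pore_radius, pore_length = pore_length,
                 z_lo = z_lo, z_hi = z_hi, axis_x = cx, axis_y = cy,
                 layers = as.integer(layers), lattice_a = a,
                 n_per_layer_full = ncols * nrows,
                 ncols = ncols, nrows = nrows),
            class = "pt_geometry")
}

# plain list for the C++ side
.geom_cpp <- function(geom) {
  list(box = geom$box, z_lo = geom$z_lo, z_hi = geom$z_hi,
       pore_radius = geom$pore_radius,
       axis_x = geom$axis_x, axis_y = geom$axis_y)
}

#' Classify a z coordinate into cis (I), pore (II) or trans (III)
#'
#' The pore interval is closed on both ends; region II wins ties. Only z is
#' used: an off-axis bead at channel z counts as II for the one-dimensional
#' monomer bookkeeping (the wall makes such positions sterically
#' inaccessible to mobile beads anyway).
#'
#' @param z z coordinate(s), already wrapped into the box
#' @param geom a [pt_geometry()]
#' @return factor with levels I, II, III
#' @export
pt_classify_region <- function(z, geom) {
  r <- ifelse(z < geom$z_lo, "I", ifelse(z <= geom$z_hi, "II", "III"))
  factor(r, levels = c("I", "II", "III"))
}

#' Is a position inside the cylindrical channel volume?
#'
#' True iff `z_lo <= z <= z_hi` and the radial distance to the pore axis is
#' at most the pore radius; this is the support of the driving field.
#'
#' @param position length-3 vector or n x 3 matrix
#' @param geom a [pt_geometry()]
#' @return logical
#' @export
pt_in_pore <- function(position, geom) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  dx <- abs(p[, 1] - geom$axis_x); dx <- pmin(dx, geom$box[1] - dx)
  dy <- abs(p[, 2] - geom$axis_y); dy <- pmin(dy, geom$box[2] - dy)
  inz <- p[, 3] >= geom$z_lo & p[, 3] <= geom$z_hi
  inz & (dx^2 + dy^2 <= geom$pore_radius^2)
}
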