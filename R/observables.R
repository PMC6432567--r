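## -------------------------------------------------------------------------
## Trajectory accessors
## -------------------------------------------------------------------------

#' Extract one frame of a trajectory as a position matrix
#'
#' @param traj a `pt_traj`
#' @param f frame index
#' @return n x 3 matrix
#' @export
pt_frame <- function(traj, f) {
  t(traj$frames[, , f])
}

# region factor of the monomers at frame f (uses z only)
.monomer_regions <- function(traj, f) {
  z <- traj$frames[3, seq_len(traj$n_monomer), f]
  ifelse(z < traj$z_lo, "I", ifelse(z <= traj$z_hi, "II", "III"))
}

#' Region-resolved radius of gyration at one frame
#'
#' `R_g,R = sqrt(sum_{i in R} (r_i - r_cm)^2 / n_R)` over the monomers in
#' region R, with the center of mass taken over the same monomer set.
#' Empty regions give NA (propagated as missing, never zero).
#'
#' @param traj a `pt_traj`
#' @param f frame index
#' @return named vector with `I`, `III`, and `tot`
#' @export
pt_frame_rg <- function(traj, f) {
  N <- traj$n_monomer
  p <- t(traj$frames[, seq_len(N), f])
  reg <- .monomer_regions(traj, f)
  rg_of <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    q <- p[idx, , drop = FALSE]
    cm <- colMeans(q)
    sqrt(mean(rowSums(sweep(q, 2, cm)^2)))
  }
  c(I = rg_of(which(reg == "I")), III = rg_of(which(reg == "III")),
    tot = rg_of(seq_len(N)))
}

#' Per-region monomer counts over a trajectory
#'
#' `N_m,III` is the translocation coordinate s. The counts must sum to N at
#' every frame; a violation is an internal-consistency error.
#'
#' @param traj a `pt_traj`
#' @return data frame with columns `time`, `I`, `II`, `III`
#' @export
pt_monomer_counts <- function(traj) {
  nf <- length(traj$time)
  m <- t(vapply(seq_len(nf), function(f) {
    reg <- .monomer_regions(traj, f)
    c(sum(reg == "I"), sum(reg == "II"), sum(reg == "III"))
  }, numeric(3)))
  if (any(rowSums(m) != traj$n_monomer))
    stop("internal-consistency error: region monomer counts do not sum to N")
  data.frame(time = traj$time, I = m[, 1], II = m[, 2], III = m[, 3])
}

#' Translocation-coordinate series of one run
#'
#' Returns the progress variable s(t) = N_m,III with the run's time axis and
#' first-passage time, the unit consumed by [pt_translocation_msd()]. The
#' synthetic generator [pt_synth_s_traj()] emits the same shape, so the
#' analysis is agnostic about its input's origin.
#'
#' @param traj a `pt_traj` with a recorded `tau`
#' @return list with `time`, `s`, `tau`
#' @export
pt_s_series <- function(traj) {
  cnt <- pt_monomer_counts(traj)
  tau <- traj$tau
  if (is.null(tau) || !is.finite(tau)) tau <- max(cnt$time)
  list(time = cnt$time, s = cnt$III, tau = tau)
}

## -------------------------------------------------------------------------
## Ensemble curves on the normalized-time grid
## -------------------------------------------------------------------------

#' Average per-run series on a normalized-time grid
#'
#' Each run's time axis is normalized by its own first-passage time
#' (t~ = t / tau) before averaging; each series is linearly interpolated
#' onto the grid. The default grid has 101 points (spacing 0.01, matching
#' the analysis window width used throughout).
#'
#' @param series list of per-run lists with `time`, `value`, `tau`
#' @param t_grid normalized-time grid in `[0, 1]`
#' @return object of class `pt_curves`: `t_grid`, `mean`, `spread`
#'   (standard deviation), `n_runs`
#' @export
pt_ensemble_curves <- function(series, t_grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(series) >= 1)
  vals <- vapply(series, function(s) {
    tt <- s$time / s$tau
    ok <- is.finite(s$value)
    if (sum(ok) < 2) return(rep(NA_real_, length(t_grid)))
    approx(tt[ok], s$value[ok], xout = t_grid, rule = 2)$y
  }, numeric(length(t_grid)))
  vals <- matrix(vals, nrow = length(t_grid))
  structure(list(t_grid = t_grid,
                 mean = rowMeans(vals, na.rm = TRUE),
                 spread = apply(vals, 1, stats::sd, na.rm = TRUE),
                 n_runs = length(series)),
            class = "pt_curves")
}

#' Region-resolved chain size on normalized time
#'
#' Ensemble-averaged R_g over the monomers in the cis region (I), the trans
#' region (III), and the whole chain (tot), on the t~ grid.
#'
#' @param trajs list of `pt_traj`
#' @param t_grid normalized-time grid
#' @return list of [pt_ensemble_curves()] results: `I`, `III`, `tot`
#' @export
pt_region_rg <- function(trajs, t_grid = seq(0, 1, by = 0.01)) {
  per_region <- function(region) {
    series <- lapply(trajs, function(tr) {
      v <- vapply(seq_along(tr$time),
                  function(f) pt_frame_rg(tr, f)[[region]], numeric(1))
      tau <- if (is.finite(tr$tau %||% NA)) tr$tau else max(tr$time)
      list(time = tr$time, value = v, tau = tau)
    })
    pt_ensemble_curves(series, t_grid)
  }
  list(I = per_region("I"), III = per_region("III"), tot = per_region("tot"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chain-end positions on normalized time
#'
#' Averaged z of the heading monomer (z1), the tail monomer (zN), and their
#' difference, measured relative to the trans-side exit plane (positive
#' into trans).
#'
#' @param trajs list of `pt_traj`
#' @param t_grid normalized-time grid
#' @return list of `pt_curves`: `z1`, `zN`, `z1_zN`
#' @export
pt_chain_ends <- function(trajs, t_grid = seq(0, 1, by = 0.01)) {
  get <- function(which_end) {
    series <- lapply(trajs, function(tr) {
      idx <- if (which_end == "z1") 1L else tr$n_monomer
      v <- traj_z(tr, idx) - tr$z_hi
      tau <- if (is.finite(tr$tau %||% NA)) tr$tau else max(tr$time)
      list(time = tr$time, value = v, tau = tau)
    })
    pt_ensemble_curves(series, t_grid)
  }
  z1 <- get("z1"); zN <- get("zN")
  diffc <- z1
  diffc$mean <- z1$mean - zN$mean
  diffc$spread <- sqrt(z1$spread^2 + zN$spread^2)
  list(z1 = z1, zN = zN, z1_zN = diffc)
}

traj_z <- function(traj, i) traj$frames[3, i, ]

#' Ensemble monomer counts per region on normalized time
#'
#' @param trajs list of `pt_traj`
#' @param t_grid normalized-time grid
#' @return list of `pt_curves`: `I`, `II`, `III`
#' @export
pt_monomer_count_curves <- function(trajs, t_grid = seq(0, 1, by = 0.01)) {
  counts <- lapply(trajs, pt_monomer_counts)
  taus <- vapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    if (is.finite(tr$tau %||% NA)) tr$tau else max(tr$time)
  }, numeric(1))
  per <- function(regname) {
    series <- lapply(seq_along(trajs), function(i)
      list(time = counts[[i]]$time, value = counts[[i]][[regname]],
           tau = taus[i]))
    pt_ensemble_curves(series, t_grid)
  }
  list(I = per("I"), II = per("II"), III = per("III"))
}

## -------------------------------------------------------------------------
## First-passage statistics and scaling fits
## -------------------------------------------------------------------------

#' Translocation-time statistics
#'
#' Mean, probability distribution P(tau) (Gaussian-kernel density estimate,
#' Silverman bandwidth), and the width w of the region where the density
#' exceeds 1/e of its peak (crossings located by linear interpolation on
#' the density grid), plus the ratio w / mean.
#'
#' @param taus first-passage times (>= 30 recommended for the distribution)
#' @return list with `mean`, `density` (x, y), `w`, `ratio`, `n`
#' @export
pt_translocation_stats <- function(taus) {
  taus <- taus[is.finite(taus)]
  if (length(taus) < 2) stop("insufficient data: need at least 2 samples")
  m <- mean(taus)
  if (stats::sd(taus) == 0)
    return(list(mean = m, density = NULL, w = 0, ratio = 0,
                n = length(taus)))
  d <- density(taus, bw = "nrd0")
  thr <- max(d$y) / exp(1)
  above <- d$y >= thr
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  cross <- function(i_lo, i_hi) {
    # interpolate the threshold crossing between grid points
    if (i_lo < 1) return(d$x[i_hi])
    x0 <- d$x[i_lo]; x1 <- d$x[i_hi]
    y0 <- d$y[i_lo]; y1 <- d$y[i_hi]
    if (y1 == y0) return(x1)
    x0 + (thr - y0) / (y1 - y0) * (x1 - x0)
  }
  lo <- cross(i1 - 1, i1)
  hi <- cross(i2 + 1, i2)
  if (i2 == length(d$y)) hi <- d$x[i2]
  w <- hi - lo
  list(mean = m, density = list(x = d$x, y = d$y), w = w, ratio = w / m,
       n = length(taus))
}

.loglog_fit <- function(x, y, regime = NA_character_, window = range(x)) {
  if (any(x <= 0) || any(y <= 0))
    stop("log-log fit requires strictly positive values")
  fit <- lm(log(y) ~ log(x))
  slope <- unname(coef(fit)[2])
  # summary.lm warns on exact power laws (zero residuals); stderr 0 is the
  # correct report there
  se <- if (length(x) > 2)
    suppressWarnings(summary(fit)$coefficients[2, 2]) else 0
  structure(list(exponent = slope, stderr = se, window = window,
                 regime = regime, n_points = length(x)),
            class = "pt_scaling_fit")
}

#' Chain-length scaling exponent alpha of the mean translocation time
#'
#' Fits `<tau> ~ N^alpha` by unweighted least squares on the log-log
#' transformed points; the standard error comes from the regression
#' residuals.
#'
#' @param tau_by_N data frame with columns `N` and `tau` (mean values)
#' @param window inclusive N range to fit
#' @return a `pt_scaling_fit` with fields `exponent`, `stderr`, `window`,
#'   `regime`
#' @export
pt_fit_alpha <- function(tau_by_N, window = range(tau_by_N$N)) {
  d <- tau_by_N[tau_by_N$N >= window[1] & tau_by_N$N <= window[2], ]
  if (nrow(d) < 2) stop("need at least 2 N values inside the fit window")
  .loglog_fit(d$N, d$tau, regime = "N-scaling", window = window)
}

#' Field-strength scaling exponents delta, one per regime
#'
#' The `<tau> ~ E^-delta` dependence splits into a weak regime (E below the
#' first break), an intermediate regime, and a strong regime (E above the
#' second break); boundary points belong to both neighbouring fits. Empty
#' regimes (fewer than 2 points) are skipped with a warning.
#'
#' @param tau_by_E data frame with columns `E` and `tau` (mean values)
#' @param breaks the two regime boundaries (default `c(1, 10)`)
#' @return named list of `pt_scaling_fit` (`weak`, `intermediate`,
#'   `strong`), each with `exponent` = delta (sign-flipped slope)
#' @export
pt_fit_delta <- function(tau_by_E, breaks = c(1, 10)) {
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  regimes <- list(
    weak = tau_by_E$E <= breaks[1],
    intermediate = tau_by_E$E >= breaks[1] & tau_by_E$E <= breaks[2],
    strong = tau_by_E$E >= breaks[2])
  out <- list()
  for (nm in names(regimes)) {
    d <- tau_by_E[regimes[[nm]], ]
    if (nrow(d) < 2) {
      warning("regime '", nm, "' has fewer than 2 field strengths; skipped")
      next
    }
    f <- .loglog_fit(d$E, d$tau, regime = nm, window = range(d$E))
    f$exponent <- -f$exponent       # report delta, not the slope
    out[[nm]] <- f
  }
  out
}

#' Mean square displacement of the translocation coordinate and its
#' late-time exponent
#'
#' `MSD(t~) = <(s(t) - s(0))^2>` on the normalized-time grid, with the
#' exponent beta fitted on `log MSD` vs `log t~` over `fit_window`
#' (default 0.5 <= t~ <= 1, the late-time regime where the scaling
#' `MSD ~ t^beta` with `alpha beta = 2` holds).
#'
#' @param s_list list of runs from [pt_s_series()] or [pt_synth_s_traj()]
#' @param fit_window normalized-time fit range within `[0, 1]`
#' @param t_grid normalized-time grid
#' @return list with `curve` (a `pt_curves` of the MSD) and `fit` (a
#'   `pt_scaling_fit` for beta)
#' @export
pt_translocation_msd <- function(s_list, fit_window = c(0.5, 1.0),
                                 t_grid = seq(0, 1, by = 0.01)) {
  if (fit_window[1] < 0 || fit_window[2] > 1 ||
      fit_window[1] >= fit_window[2])
    stop("fit window must lie inside [0, 1]")
  series <- lapply(s_list, function(s)
    list(time = s$time, value = (s$s - s$s[1])^2, tau = s$tau))
  curve <- pt_ensemble_curves(series, t_grid)
  sel <- curve$t_grid >= fit_window[1] & curve$t_grid <= fit_window[2] &
    curve$t_grid > 0 & is.finite(curve$mean) & curve$mean > 0
  if (sum(sel) < 2) stop("not enough points in the MSD fit window")
  fit <- .loglog_fit(curve$t_grid[sel], curve$mean[sel],
                     regime = "late-time", window = fit_window)
  list(curve = curve, fit = fit)
}

## -------------------------------------------------------------------------
## Ion condensation
## -------------------------------------------------------------------------

#' Condensed-ion accounting for one frame
#'
#' An ion is condensed if its minimum-image distance to the nearest monomer
#' is smaller than the Bjerrum length. Each condensed ion is attributed to
#' the region (I/II/III) of its nearest monomer (condensation is a
#' chain-relative property). The record carries the per-region counts of
#' condensed counter-charges (+1) and co-charges (-1), the total condensed
#' charge `Qc = e Nc(+1) - e Nc(-1)`, and the neutralized fraction
#' `|Qc / (N e)|`.
#'
#' @param frame either a `pt_traj` (with `frame_index`) or a list with
#'   `pos`, `charge`, `species`, `n_monomer`, `box`, `z_lo`, `z_hi`
#' @param frame_index frame number when `frame` is a trajectory
#' @param lambda_B Bjerrum length (condensation cutoff)
#' @return object of class `pt_condensation`: `Nc_plus`, `Nc_minus` (named
#'   I/II/III), `Qc`, `fraction`
#' @export
pt_condensation <- function(frame, frame_index = NULL, lambda_B = 3.0) {
  fr <- .as_frame(frame, frame_index)
  N <- fr$n_monomer
  mono <- fr$pos[seq_len(N), , drop = FALSE]
  ions <- which(seq_len(nrow(fr$pos)) > N & fr$charge != 0)
  regs <- c("I", "II", "III")
  ncp <- setNames(numeric(3), regs)
  ncm <- setNames(numeric(3), regs)
  if (length(ions)) {
    mono_reg <- ifelse(mono[, 3] < fr$z_lo, "I",
                       ifelse(mono[, 3] <= fr$z_hi, "II", "III"))
    for (i in ions) {
      dd <- abs(sweep(mono, 2, fr$pos[i, ]))
      for (k in 1:3) dd[, k] <- pmin(dd[, k], fr$box[k] - dd[, k])
      d2 <- rowSums(dd^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) < lambda_B) {
        r <- mono_reg[j]
        if (fr$charge[i] > 0) ncp[r] <- ncp[r] + 1 else ncm[r] <- ncm[r] + 1
      }
    }
  }
  Qc <- sum(ncp) - sum(ncm)
  structure(list(Nc_plus = ncp, Nc_minus = ncm, Qc = Qc,
                 fraction = abs(Qc / N)),
            class = "pt_condensation")
}

.as_frame <- function(frame, frame_index) {
  if (inherits(frame, "pt_traj")) {
    stopifnot(!is.null(frame_index))
    list(pos = pt_frame(frame, frame_index), charge = frame$charge,
         species = frame$species, n_monomer = frame$n_monomer,
         box = frame$box, z_lo = frame$z_lo, z_hi = frame$z_hi)
  } else {
    stopifnot(is.list(frame), !is.null(frame$pos))
    frame
  }
}

#' Manning prediction for the condensed line charge density
#'
#' Counterion condensation reduces the magnitude of the line charge density
#' of a highly charged chain to `e / lambda_B`.
#'
#' @param lambda_B Bjerrum length (> 0)
#' @return line charge density in e/sigma
#' @export
pt_manning_reference <- function(lambda_B) {
  if (any(lambda_B <= 0)) stop("lambda_B must be positive")
  1 / lambda_B
}

#' Contour length and effective line charge density of the chain
#'
#' The contour length is the sum of the bond lengths; the effective line
#' charge density combines the bare chain charge with the condensed-ion
#' charge: `|(-N e + Qc) / l|`.
#'
#' @inheritParams pt_condensation
#' @return list with `contour` (sigma), `density` (e/sigma), `Qc`, and the
#'   condensation record
#' @export
pt_line_density <- function(frame, frame_index = NULL, lambda_B = 3.0) {
  fr <- .as_frame(frame, frame_index)
  N <- fr$n_monomer
  p <- fr$pos[seq_len(N), , drop = FALSE]
  d <- abs(p[-1, , drop = FALSE] - p[-N, , drop = FALSE])
  for (k in 1:3) d[, k] <- pmin(d[, k], fr$box[k] - d[, k])
  ell <- sum(sqrt(rowSums(d^2)))
  cond <- pt_condensation(fr, lambda_B = lambda_B)
  list(contour = ell, density = abs((-N + cond$Qc) / ell),
       Qc = cond$Qc, condensation = cond)
}

## -------------------------------------------------------------------------
## Spatial distributions
## -------------------------------------------------------------------------

#' Species-resolved probability profiles along z in normalized-time windows
#'
#' For each requested window `[t~, t~ + width]`, pools the frames of all
#' runs whose normalized time falls inside and histograms the z positions
#' of monomers, +1 ions, and -1 ions into bins of `bin` sigma, normalized
#' to unit integral over z. Empty windows yield a missing profile with a
#' warning.
#'
#' @param trajs list of `pt_traj`
#' @param t_windows left edges of the normalized-time windows
#' @param width window width (default 0.01)
#' @param bin histogram bin width in sigma (default 0.5)
#' @return named list (one element per window, names the t~ values) of
#'   data frames with columns `z`, `P_m`, `P_plus`, `P_minus`
#' @export
pt_z_profiles <- function(trajs, t_windows = c(0), width = 0.01, bin = 0.5) {
  box_z <- trajs[[1]]$box[3]
  edges <- seq(0, box_z + bin, by = bin)
  mids <- edges[-length(edges)] + bin / 2
  out <- list()
  for (tw in t_windows) {
    zm <- c(); zp <- c(); zn <- c()
    for (tr in trajs) {
      tau <- if (is.finite(tr$tau %||% NA)) tr$tau else max(tr$time)
      sel <- which(tr$time / tau >= tw & tr$time / tau <= tw + width)
      for (f in sel) {
        z <- tr$frames[3, , f]
        mono <- seq_len(tr$n_monomer)
        zm <- c(zm, z[mono])
        ion <- setdiff(seq_along(z), mono)
        zp <- c(zp, z[ion][tr$charge[ion] > 0])
        zn <- c(zn, z[ion][tr$charge[ion] < 0])
      }
    }
    if (!length(zm)) {
      warning("no frames in window [", tw, ", ", tw + width, "]")
      out[[as.character(tw)]] <- NULL
      next
    }
    histo <- function(z) {
      if (!length(z)) return(rep(NA_real_, length(mids)))
      h <- tabulate(pmin(findInterval(z, edges), length(mids)),
                    nbins = length(mids))
      h / (sum(h) * bin)
    }
    out[[as.character(tw)]] <- data.frame(z = mids, P_m = histo(zm),
                                          P_plus = histo(zp),
                                          P_minus = histo(zn))
  }
  out
}

#' Monomer density map in the y-z plane
#'
#' Counts monomer positions integrated over x on a (y, z) grid, normalized
#' per pooled frame, for the frames whose normalized time falls inside the
#' window.
#'
#' @param trajs list of `pt_traj`
#' @param window normalized-time window `c(lo, hi)` (default the whole run)
#' @param cell grid cell edge in sigma
#' @return list with `y`, `z` (cell centers) and `density` (matrix, y rows)
#' @export
pt_density_map <- function(trajs, window = c(0, 1), cell = 1.0) {
  box <- trajs[[1]]$box
  ye <- seq(0, box[2] + cell, by = cell)
  ze <- seq(0, box[3] + cell, by = cell)
  ny <- length(ye) - 1; nz <- length(ze) - 1
  m <- matrix(0, ny, nz)
  nfr <- 0L
  for (tr in trajs) {
    tau <- if (is.finite(tr$tau %||% NA)) tr$tau else max(tr$time)
    sel <- which(tr$time / tau >= window[1] & tr$time / tau <= window[2])
    for (f in sel) {
      y <- tr$frames[2, seq_len(tr$n_monomer), f]
      z <- tr$frames[3, seq_len(tr$n_monomer), f]
      iy <- pmin(findInterval(y, ye), ny)
      iz <- pmin(findInterval(z, ze), nz)
      for (k in seq_along(iy)) m[iy[k], iz[k]] <- m[iy[k], iz[k]] + 1
      nfr <- nfr + 1L
    }
  }
  if (nfr == 0) stop("no frames inside the requested window")
  list(y = ye[-length(ye)] + cell / 2, z = ze[-length(ze)] + cell / 2,
       density = m / nfr)
}

#' Peak position of a pooled monomer z sample
#'
#' Histograms the pooled z values (bin width `bin`), smooths the counts
#' with a short moving average to stabilize the argmax against counting
#' noise, and returns the peak bin center. Used to measure the
#' peak-to-wall distance of the monomer profile at t~ = 0.
#'
#' @param z pooled z coordinates
#' @param z_max histogram upper edge (defaults to `max(z) + bin`)
#' @param bin bin width in sigma
#' @param smooth moving-average window in bins (odd; 1 = no smoothing)
#' @return the z of the (smoothed) histogram peak
#' @export
pt_profile_peak <- function(z, z_max = NULL, bin = 0.5, smooth = 5L) {
  stopifnot(length(z) > 0, smooth >= 1, smooth %% 2 == 1)
  if (is.null(z_max)) z_max <- max(z) + bin
  edges <- seq(0, z_max + bin, by = bin)
  mids <- edges[-length(edges)] + bin / 2
  h <- tabulate(pmin(findInterval(z, edges), length(mids)),
                nbins = length(mids))
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    h <- as.numeric(stats::filter(h, k, sides = 2))
    h[is.na(h)] <- 0
  }
  mids[which.max(h)]
}
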