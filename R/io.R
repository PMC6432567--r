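## Configuration, trajectory and table I/O. Everything is in reduced units
## (sigma, m, tau_u, e); see the package help page for the mapping to
## physical units, which never appears in files.

.config_defaults <- function() {
  list(model = unclass(pt_model_params()),
       run = list(N = 128L, E = 1.0, n_salt_cations = 256L,
                  n_salt_anions = 256L, equilibration_steps = 20000L,
                  max_steps = 2000000L, seed = 1L, frame_every = 200L),
       langevin = list(dt = NA_real_),   # NA = pt_default_dt(E)
       ewald = list(accuracy = 1e-3),
       geometry = list(box = c(48.0, 49.36, 200.0), pore_radius = 2.25,
                       pore_length = 4.5, layers = 4L))
}

#' Read a run configuration file
#'
#' YAML with up to five sections (`model`, `run`, `langevin`, `ewald`,
#' `geometry`); every omitted key takes its production default, so an empty
#' file yields the full default parameter set. Unknown sections or keys are
#' rejected by name; out-of-range values raise descriptive errors.
#'
#' @param path configuration file
#' @return list with `model` ([pt_model_params()]), `run`
#'   ([pt_run_config()]), `langevin` (list with `dt`, possibly NA),
#'   `ewald` ([pt_ewald_params()]), `geometry` ([pt_geometry()])
#' @export
pt_read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- .config_defaults()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    def[[sec]] <- modifyList(def[[sec]], raw[[sec]])
  }
  model <- do.call(pt_model_params, def$model)
  run <- do.call(pt_run_config, def$run)
  geometry <- do.call(pt_geometry, def$geometry)
  ewald <- pt_ewald_params(geometry$box, accuracy = def$ewald$accuracy)
  list(model = model, run = run, langevin = def$langevin,
       ewald = ewald, geometry = geometry)
}

#' Write a run configuration file
#'
#' Round-trips with [pt_read_config()].
#'
#' @param cfg list as returned by [pt_read_config()], or a partial list of
#'   sections
#' @param path output path
#' @export
pt_write_config <- function(cfg, path) {
  out <- list()
  if (!is.null(cfg$model)) out$model <- unclass(cfg$model)
  if (!is.null(cfg$run)) out$run <- unclass(cfg$run)
  if (!is.null(cfg$langevin) && is.finite(cfg$langevin$dt %||% NA))
    out$langevin <- list(dt = cfg$langevin$dt)
  if (!is.null(cfg$ewald)) out$ewald <- list(accuracy = cfg$ewald$accuracy)
  if (!is.null(cfg$geometry))
    out$geometry <- cfg$geometry[c("box", "pore_radius", "pore_length",
                                   "layers")]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write / read a trajectory container
#'
#' Bulk storage uses R's native serialization with a versioned layout
#' (frames as a 3 x n x n_frames array plus per-frame times, species,
#' charges, box and region planes); see [pt_write_xyz()] for text
#' snapshots. A truncated or foreign file raises an explicit corruption
#' error on read.
#'
#' @param traj a `pt_traj`
#' @param path output file
#' @return the path, invisibly
#' @export
pt_write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pt_traj"))
  payload <- list(format = "polytrans-traj", version = 1L,
                  data = unclass(traj))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname pt_write_trajectory
#' @export
pt_read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("corrupt trajectory file: ",
                                               path, " (", conditionMessage(e),
                                               ")"))
  if (!is.list(payload) || !identical(payload$format, "polytrans-traj"))
    stop("corrupt trajectory file: ", path, " (unrecognized layout)")
  structure(payload$data, class = "pt_traj")
}

.species_element <- c(monomer = "C", counterion = "N", cation = "P",
                      anion = "O", neutral = "H", wall = "W")

#' Export a snapshot as XYZ
#'
#' Standard XYZ: atom count, comment line, then one `element x y z` row per
#' bead. Species map to element tags C (monomer), N (counterion),
#' P (cation), O (anion), W (wall).
#'
#' @param positions n x 3 matrix
#' @param species character vector of bead species
#' @param path output file
#' @param comment comment line
#' @return the path, invisibly
#' @export
pt_write_xyz <- function(positions, species, path, comment = "polytrans") {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(species))
  el <- .species_element[species]
  el[is.na(el)] <- "X"
  lines <- c(nrow(positions), comment,
             sprintf("%s %.6f %.6f %.6f", el,
                     positions[, 1], positions[, 2], positions[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Export the wall coordinates as XYZ
#'
#' @param geom a [pt_geometry()]
#' @param path output file
#' @export
pt_wall_xyz <- function(geom, path) {
  pt_write_xyz(geom$wall, rep("wall", nrow(geom$wall)), path,
               comment = "membrane wall beads")
}

#' Export a single frame as PDB
#'
#' Uses bio3d when available; intended for quick visualization of single
#' snapshots only.
#'
#' @param positions n x 3 matrix
#' @param species bead species
#' @param path output file
#' @export
pt_write_pdb <- function(positions, species, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("PDB export needs the bio3d package")
  el <- .species_element[species]
  el[is.na(el)] <- "X"
  bio3d::write.pdb(file = path, xyz = as.numeric(t(positions)),
                   elety = el, resno = seq_along(species),
                   chain = rep("A", length(species)))
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit on one
#' platform: all parameter bundles, the seed, the time step actually used,
#' completion status and the first-passage time. Written atomically
#' (temp file + rename).
#'
#' @param path output JSON file
#' @param model,run,ewald parameter bundles
#' @param dt time step actually used
#' @param seed seed actually used
#' @param completed,tau run outcome
#' @param extra optional named list merged into the manifest
#' @return the manifest list, invisibly
#' @export
pt_write_manifest <- function(path, model, run, ewald = NULL, dt = NA,
                              seed = NA, completed = NA, tau = NA,
                              extra = list()) {
  man <- c(list(package = "polytrans",
                version = as.character(utils::packageVersion("polytrans")),
                model = unclass(model), run = unclass(run),
                ewald = if (!is.null(ewald))
                  unclass(ewald)[c("accuracy", "alpha", "r_cut")] else NULL,
                dt = dt, seed = seed, completed = completed, tau = tau),
           extra)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)
  invisible(man)
}

#' Export an ensemble-curve object as a tidy table
#'
#' @param curves a `pt_curves`
#' @param path optional CSV output path
#' @return data frame with one row per grid point
#' @export
pt_curves_table <- function(curves, path = NULL) {
  d <- data.frame(t = curves$t_grid, mean = curves$mean,
                  spread = curves$spread, n_runs = curves$n_runs)
  if (!is.null(path)) write.csv(d, path, row.names = FALSE)
  d
}
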