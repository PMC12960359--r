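#' Write a trajectory snapshot in the LAMMPS dump text dialect
#'
#' Emits `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS / ATOMS id type x
#' y z vx vy vz` blocks; multiple snapshots may be appended to one file.
#' Kinds are written as 1-based types (1 plasma, 2 wall, 3 coated
#' surface, 4 platelet).
#'
#' @param snapshot Matrix with columns (id, kind, x, y, z, vx, vy, vz) as
#'   produced by [dpd_run()] snapshots, or a [particle_system()].
#' @param box Length-3 box extents (taken from the system if given one).
#' @param step Timestep index written to the header.
#' @param path Output file.
#' @param wall_pad y-padding of the wall slabs included in the bounds.
#' @param append Append to an existing file (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_lammps_dump <- function(snapshot, box = NULL, step = 0, path,
                              wall_pad = 1, append = FALSE) {
  if (inherits(snapshot, "particle_system")) {
    box <- snapshot$box
    wall_pad <- snapshot$wall_pad
    snapshot <- cbind(seq_len(nrow(snapshot$x)), snapshot$kind,
                      snapshot$x, snapshot$v)
  }
  if (is.null(box)) stop("'box' is required for matrix snapshots", call. = FALSE)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(
    "ITEM: TIMESTEP", format(step, scientific = FALSE),
    "ITEM: NUMBER OF ATOMS", format(nrow(snapshot), scientific = FALSE),
    "ITEM: BOX BOUNDS pp ff pp",
    sprintf("%.8g %.8g", 0, box[1]),
    sprintf("%.8g %.8g", -wall_pad, box[2] + wall_pad),
    sprintf("%.8g %.8g", 0, box[3]),
    "ITEM: ATOMS id type x y z vx vy vz"
  ), con)
  writeLines(sprintf("%d %d %.8g %.8g %.8g %.8g %.8g %.8g",
                     as.integer(snapshot[, 1]), as.integer(snapshot[, 2]) + 1L,
                     snapshot[, 3], snapshot[, 4], snapshot[, 5],
                     snapshot[, 6], snapshot[, 7], snapshot[, 8]), con)
  invisible(path)
}

#' Write a snapshot in XYZ format
#'
#' Minimal XYZ dialect: atom count, comment line, then
#' `element x y z` rows with the kind name as the element label.
#'
#' @inheritParams write_lammps_dump
#' @export
write_xyz <- function(snapshot, step = 0, path, append = FALSE) {
  if (inherits(snapshot, "particle_system")) {
    snapshot <- cbind(seq_len(nrow(snapshot$x)), snapshot$kind,
                      snapshot$x, snapshot$v)
  }
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(format(nrow(snapshot), scientific = FALSE),
               sprintf("step %s", format(step, scientific = FALSE))), con)
  writeLines(sprintf("%s %.8g %.8g %.8g",
                     KIND_LEVELS[as.integer(snapshot[, 2]) + 1L],
                     snapshot[, 3], snapshot[, 4], snapshot[, 5]), con)
  invisible(path)
}

#' Write all outputs of a simulation run
#'
#' Writes the metrics series (`metrics.csv`, units in the header), the
#' bond event log (`bond_events.csv`), the per-step diagnostics
#' (`diagnostics.csv`), the resolved configuration (`config.yaml`), the
#' final state (`final.dump`) and any recorded snapshots
#' (`trajectory.dump`).
#'
#' @param run A `dpd_simulation` from [run_simulation()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "metrics.csv")
  m <- run$metrics_df
  names(m) <- c("time_s", "covered_area_percent", "adhered_count")
  utils::write.csv(m, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "diagnostics.csv")
  d <- data.frame(step = run$metrics$step, time_dpd = run$metrics$time,
                  n_platelets = run$metrics$n_platelets,
                  n_adhered = run$metrics$n_adhered,
                  n_bonds = run$metrics$n_bonds,
                  temperature_kBT = run$metrics$temperature,
                  mean_plasma_vx_dpd = run$metrics$mean_plasma_vx)
  utils::write.csv(d, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "bond_events.csv")
  ev <- as.data.frame(run$events)
  ev$type <- c("form", "break", "promote", "out_of_range", "evaporate")[ev$type]
  utils::write.csv(ev, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  if (!is.null(run$config)) {
    p <- file.path(dir, "config.yaml")
    save_run_config(run$config, p)
    paths <- c(paths, p)
  }

  p <- file.path(dir, "final.dump")
  snap <- cbind(run$id, run$kind, run$x, run$v)
  write_lammps_dump(snap, box = run$box, step = run$final_step, path = p,
                    wall_pad = run$system$wall_pad)
  paths <- c(paths, p)

  if (length(run$snapshots)) {
    p <- file.path(dir, "trajectory.dump")
    for (i in seq_along(run$snapshots)) {
      write_lammps_dump(run$snapshots[[i]], box = run$box,
                        step = run$snapshot_steps[i], path = p,
                        wall_pad = run$system$wall_pad, append = i > 1)
    }
    paths <- c(paths, p)
  }
  paths
}

#' Read a LAMMPS dump snapshot
#'
#' Parses the first snapshot of a text dump written by
#' [write_lammps_dump()] (columns `id type x y z vx vy vz`).
#'
#' @param path Dump file path.
#' @return List with `x`, `v` (N x 3 matrices ordered by id), `kind`
#'   (0-based), `id`, `box`, `step`.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ITEM: TIMESTEP") stop("not a LAMMPS dump file", call. = FALSE)
  step <- as.numeric(lines[2])
  n <- as.integer(lines[4])
  bounds <- do.call(rbind, lapply(strsplit(lines[6:8], " "), as.numeric))
  header <- 9L
  dat <- utils::read.table(text = lines[(header + 1):(header + n)])
  ord <- order(dat[[1]])
  dat <- dat[ord, ]
  list(
    x = unname(as.matrix(dat[, 3:5])),
    v = unname(as.matrix(dat[, 6:8])),
    kind = as.integer(dat[[2]]) - 1L,
    id = as.integer(dat[[1]]),
    box = c(bounds[1, 2] - bounds[1, 1], NA, bounds[3, 2] - bounds[3, 1]),
    step = step
  )
}
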