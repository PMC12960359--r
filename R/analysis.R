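#' Platelet-covered area fraction of the floor
#'
#' Rasterizes the coated floor and reports the fraction of raster cells
#' whose centre lies within one projected platelet radius of any adhered
#' platelet centre; overlapping platelets are not double counted. This is
#' the simulation analogue of the covered-area percentage measured from
#' fluorescence projections.
#'
#' @param positions Matrix of adhered platelet centres: columns x, z
#'   (projected), or x, y, z (y is ignored).
#' @param diameter Platelet diameter in the same length units.
#' @param floor_x,floor_z Length-2 extents of the floor.
#' @param resolution Raster cell edge; must be at most `diameter / 6`
#'   (default `diameter / 12`, about 2% disk-area error).
#' @return Covered fraction in `[0, 1]`.
#' @export
covered_area_fraction <- function(positions, diameter,
                                  floor_x, floor_z,
                                  resolution = diameter / 12) {
  if (diff(floor_x) <= 0 || diff(floor_z) <= 0)
    stop("floor extents must be non-empty", call. = FALSE)
  if (resolution > diameter / 6 + 1e-12)
    stop("'resolution' must be at most diameter / 6", call. = FALSE)
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) return(0)
  px <- positions[, 1]
  pz <- positions[, ncol(positions)]  # (x, z) or (x, y, z)
  nx <- max(1L, ceiling(diff(floor_x) / resolution))
  nz <- max(1L, ceiling(diff(floor_z) / resolution))
  hx <- diff(floor_x) / nx
  hz <- diff(floor_z) / nz
  covered <- matrix(FALSE, nx, nz)
  r <- diameter / 2
  r2 <- r^2
  for (k in seq_along(px)) {
    i0 <- max(1L, floor((px[k] - r - floor_x[1]) / hx) + 1L)
    i1 <- min(nx, ceiling((px[k] + r - floor_x[1]) / hx))
    j0 <- max(1L, floor((pz[k] - r - floor_z[1]) / hz) + 1L)
    j1 <- min(nz, ceiling((pz[k] + r - floor_z[1]) / hz))
    if (i0 > i1 || j0 > j1) next
    ci <- floor_x[1] + (i0:i1 - 0.5) * hx
    cj <- floor_z[1] + (j0:j1 - 0.5) * hz
    d2 <- outer((ci - px[k])^2, (cj - pz[k])^2, `+`)
    covered[i0:i1, j0:j1] <- covered[i0:i1, j0:j1] | (d2 <= r2)
  }
  mean(covered)
}

#' Partition adhered platelets into aggregates
#'
#' Connected components of the pairwise contact relation (centre distance
#' at most `contact_distance`), with the per-aggregate projected area
#' computed by the covered-area raster restricted to the component, and
#' the maximum height as the highest platelet centre above the floor.
#'
#' @param positions N x 3 matrix of adhered platelet centres (x, y, z; y
#'   is the wall-normal height).
#' @param diameter Platelet diameter.
#' @param contact_distance Contact threshold (default `1.1 * diameter`).
#' @param floor_level y of the floor plane (default 0).
#' @param units Optional [dpd_units()]; when given, `projected_area` is
#'   reported in square microns and `max_height` in microns, otherwise in
#'   DPD units.
#' @param resolution Raster resolution for areas (default `diameter / 12`).
#' @return data.frame with columns `aggregate`, `n_platelets`,
#'   `projected_area`, `max_height`, ordered by decreasing size.
#' @export
platelet_aggregates <- function(positions, diameter,
                                contact_distance = 1.1 * diameter,
                                floor_level = 0, units = NULL,
                                resolution = diameter / 12) {
  if (contact_distance <= 0) stop("'contact_distance' must be positive", call. = FALSE)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  empty <- data.frame(aggregate = integer(), n_platelets = integer(),
                      projected_area = numeric(), max_height = numeric())
  if (n == 0) return(empty)
  d <- as.matrix(stats::dist(positions))
  adj <- d <= contact_distance
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  r <- diameter / 2
  scale_l <- if (is.null(units)) 1 else units$length / 1e-6  # microns per DPD length
  rows <- lapply(sort(unique(comp)), function(cid) {
    idx <- which(comp == cid)
    px <- positions[idx, 1]; pz <- positions[idx, 3]
    fx <- range(px) + c(-r - resolution, r + resolution)
    fz <- range(pz) + c(-r - resolution, r + resolution)
    frac <- covered_area_fraction(cbind(px, pz), diameter, fx, fz, resolution)
    area <- frac * diff(fx) * diff(fz) * scale_l^2
    data.frame(aggregate = cid, n_platelets = length(idx),
               projected_area = area,
               max_height = (max(positions[idx, 2]) - floor_level) * scale_l)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_platelets, out$aggregate), , drop = FALSE]
  out$aggregate <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fraction of adhered platelets in a single layer
#'
#' A platelet is "covered" when another adhered platelet rests on top of
#' it: the pair is within contact range (centre distance at most two
#' diameters), the height difference exceeds 0.6 diameters, and the
#' vertical offset dominates the horizontal one (more above than beside —
#' this excludes diagonal packing within a crowded single layer).
#' VWF-like monolayer adhesion gives a fraction near 1; collagen-like
#' multilayer aggregation reduces it.
#'
#' @inheritParams platelet_aggregates
#' @return Fraction in `[0, 1]` of platelets with no platelet above them,
#'   or `NA` when there are no platelets.
#' @export
monolayer_fraction <- function(positions, diameter) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n == 0) return(NA_real_)
  covered <- logical(n)
  for (i in seq_len(n)) {
    dxz <- sqrt((positions[, 1] - positions[i, 1])^2 +
                  (positions[, 3] - positions[i, 3])^2)
    dy <- positions[, 2] - positions[i, 2]
    covered[i] <- any(dy > 0.6 * diameter & dy > dxz &
                        dxz^2 + dy^2 <= (2 * diameter)^2)
  }
  mean(!covered)
}

#' Mean streamwise velocity profile across the channel
#'
#' Bins mobile-particle x-velocities by wall-normal position y. Accepts
#' either a [particle_system()] (instantaneous profile) or the profile
#' accumulator returned by [dpd_run()] (time-averaged profile).
#'
#' @param system A [particle_system()], or a `dpd_run` result with a
#'   profile accumulator.
#' @param n_bins Number of y bins (ignored for accumulators, whose bin
#'   count is fixed at run time); at least 4.
#' @param kinds Particle kinds to include (default plasma).
#' @return data.frame with `y` (bin centre), `mean_vx`, `se` (standard
#'   error), `n`; empty bins carry `NA`, not zero.
#' @export
velocity_profile <- function(system, n_bins = 20, kinds = KIND_PLASMA) {
  if (inherits(system, "dpd_run")) {
    pr <- system$profile
    if (sum(pr$n) == 0) stop("run has no profile accumulator", call. = FALSE)
    nb <- length(pr$n)
    y <- (seq_len(nb) - 0.5) * system$box[2] / nb
    m <- ifelse(pr$n > 0, pr$vx_sum / pr$n, NA_real_)
    vr <- ifelse(pr$n > 1, pmax(pr$vx_sum2 / pr$n - m^2, 0), NA_real_)
    return(data.frame(y = y, mean_vx = m,
                      se = sqrt(vr / pmax(pr$n, 1)), n = pr$n))
  }
  stopifnot(inherits(system, "particle_system"))
  if (n_bins < 4) stop("'n_bins' must be at least 4", call. = FALSE)
  sel <- system$kind %in% kinds
  y <- system$x[sel, 2]
  vx <- system$v[sel, 1]
  H <- system$box[2]
  bin <- pmin(pmax(floor(y / H * n_bins) + 1L, 1L), n_bins)
  out <- data.frame(y = (seq_len(n_bins) - 0.5) * H / n_bins,
                    mean_vx = NA_real_, se = NA_real_, n = 0L)
  agg_n <- tabulate(bin, n_bins)
  out$n <- agg_n
  has <- agg_n > 0
  out$mean_vx[has] <- vapply(which(has), function(b) mean(vx[bin == b]), 0)
  out$se[has] <- vapply(which(has), function(b) {
    v <- vx[bin == b]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, 0)
  out
}

#' Polynomial fit of the velocity profile and wall shear rate
#'
#' Least-squares polynomial fit of mean x-velocity against y; the wall
#' shear rate is the magnitude of the fitted derivative at the wall
#' plane, optionally converted to physical 1/s through the unit system.
#' Both walls are evaluated and the mean reported (they agree for a
#' symmetric profile).
#'
#' @param profile data.frame from [velocity_profile()].
#' @param degree Polynomial degree (default 2).
#' @param H Channel height; defaults to twice the largest bin centre.
#' @param units Optional [dpd_units()] for conversion to 1/s.
#' @return List with `coefficients` (increasing powers of y),
#'   `wall_shear_rate` (DPD units), `wall_shear_rate_per_s` (`NA` without
#'   `units`) and `fitted` (function of y).
#' @export
fit_profile_shear <- function(profile, degree = 2, H = NULL, units = NULL) {
  if (degree < 2) stop("'degree' must be at least 2", call. = FALSE)
  ok <- is.finite(profile$mean_vx)
  if (sum(ok) < degree + 2)
    stop("not enough valid bins for a degree-", degree, " fit", call. = FALSE)
  y <- profile$y[ok]
  u <- profile$mean_vx[ok]
  if (is.null(H)) H <- 2 * max(profile$y)
  fit <- stats::lm(u ~ stats::poly(y, degree, raw = TRUE))
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0
  dcoef <- beta[-1] * seq_len(degree)
  dpoly <- function(yy) vapply(yy, function(p) sum(dcoef * p^(seq_len(degree) - 1)), 0)
  shear <- mean(abs(dpoly(c(0, H))))
  list(
    coefficients = unname(beta),
    wall_shear_rate = shear,
    wall_shear_rate_per_s = if (is.null(units)) NA_real_ else shear / units$time,
    fitted = function(yy) vapply(yy, function(p) sum(beta * p^(0:degree)), 0)
  )
}

#' Near-wall platelet speed histogram
#'
#' Percentage of platelets within `wall_distance` of the coated floor in
#' each speed class. Class edges are physical velocities (m/s) when a
#' unit system is supplied, otherwise DPD velocities.
#'
#' @param system A [particle_system()].
#' @param wall_distance Height band above the floor (DPD length, default 1).
#' @param edges Increasing vector of class edges (the first class is
#'   below `edges[1]`, the last above `edges[length(edges)]`).
#' @param units Optional [dpd_units()]; when given, `edges` are in m/s.
#' @return data.frame with `class` (label), `percent`; percentages sum to
#'   100 when any platelet qualifies, zero rows otherwise.
#' @export
near_wall_speed_histogram <- function(system, wall_distance = 1, edges,
                                      units = NULL) {
  stopifnot(inherits(system, "particle_system"))
  if (wall_distance <= 0) stop("'wall_distance' must be positive", call. = FALSE)
  if (is.unsorted(edges, strictly = TRUE)) stop("'edges' must be increasing", call. = FALSE)
  sel <- system$kind == KIND_PLATELET & system$x[, 2] <= wall_distance
  if (!any(sel)) {
    return(data.frame(class = character(), percent = numeric()))
  }
  speed <- sqrt(rowSums(system$v[sel, , drop = FALSE]^2))
  if (!is.null(units)) speed <- speed * units$velocity
  br <- c(-Inf, edges, Inf)
  cls <- cut(speed, breaks = br)
  lab <- c(paste0("< ", edges[1]),
           if (length(edges) > 1)
             paste(edges[-length(edges)], "-", edges[-1]),
           paste0("> ", edges[length(edges)]))
  data.frame(class = lab,
             percent = 100 * as.numeric(table(cls)) / length(speed))
}

#' Coarse-grained velocity and shear-stress fields
#'
#' Averages plasma velocities on an x-y grid (averaged over z) and
#' estimates the shear stress as `mu_eff` times the central-difference
#' gradient of the mean x-velocity across y. Cells without particles are
#' `NA`.
#'
#' @param system A [particle_system()].
#' @param nx,ny Grid shape (default 40 x 10).
#' @param mu_eff Effective dynamic viscosity in DPD units used to scale
#'   the stress field (default 1; measure it once per run from the steady
#'   profile).
#' @return List with `x`, `y` (cell centres), `speed` (nx x ny mean
#'   velocity magnitude), `vx` (mean x-velocity) and `shear_stress`
#'   (nx x ny, DPD units).
#' @export
coarse_field <- function(system, nx = 40, ny = 10, mu_eff = 1) {
  stopifnot(inherits(system, "particle_system"))
  sel <- system$kind == KIND_PLASMA
  pos <- system$x[sel, , drop = FALSE]
  vel <- system$v[sel, , drop = FALSE]
  Lx <- system$box[1]; Ly <- system$box[2]
  ix <- pmin(pmax(floor(pos[, 1] / Lx * nx) + 1L, 1L), nx)
  iy <- pmin(pmax(floor(pos[, 2] / Ly * ny) + 1L, 1L), ny)
  cell <- (iy - 1L) * nx + ix
  cnt <- tabulate(cell, nx * ny)
  sum_vx <- rowsum(vel[, 1], cell)
  sum_sp <- rowsum(sqrt(rowSums(vel^2)), cell)
  vx <- matrix(NA_real_, nx, ny)
  sp <- matrix(NA_real_, nx, ny)
  idx <- as.integer(rownames(sum_vx))
  vx[idx] <- sum_vx[, 1] / cnt[idx]
  sp[idx] <- sum_sp[, 1] / cnt[idx]
  hy <- Ly / ny
  dudy <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) {
    jm <- max(1L, j - 1L); jp <- min(ny, j + 1L)
    dudy[, j] <- (vx[, jp] - vx[, jm]) / ((jp - jm) * hy)
  }
  list(x = (seq_len(nx) - 0.5) * Lx / nx,
       y = (seq_len(ny) - 0.5) * Ly / ny,
       speed = sp, vx = vx, shear_stress = mu_eff * abs(dudy))
}

#' Covered-area and adhesion time series from a run
#'
#' Converts the adhered-platelet snapshots recorded by [dpd_run()] or
#' [run_simulation()] into the tidy metrics series: physical time,
#' covered-area percentage of the floor, and adhered platelet count.
#'
#' @param run A `dpd_run` result with `metrics_every > 0`.
#' @param diameter Platelet diameter (DPD length units).
#' @param units Optional [dpd_units()]; when given, `time_s` is seconds,
#'   otherwise DPD time.
#' @param resolution Raster resolution (default `diameter / 12`).
#' @return data.frame with `time_s`, `covered_area_percent`,
#'   `adhered_count`.
#' @export
metrics_series <- function(run, diameter = 0.6, units = NULL,
                           resolution = diameter / 12) {
  stopifnot(inherits(run, "dpd_run"))
  snaps <- run$adhered_snapshots
  tt <- run$metrics$time
  Lx <- run$box[1]; Lz <- run$box[3]
  cov <- vapply(seq_along(snaps), function(i) {
    s <- snaps[[i]]
    if (nrow(s) == 0) return(0)
    covered_area_fraction(s[, c(2, 4), drop = FALSE], diameter,
                          c(0, Lx), c(0, Lz), resolution)
  }, 0)
  data.frame(
    time_s = if (is.null(units)) tt else tt * units$time,
    covered_area_percent = 100 * cov,
    adhered_count = run$metrics$n_adhered
  )
}

#' Window-averaged platelet drift speeds
#'
#' Instantaneous DPD velocities are dominated by thermal noise (the
#' thermal speed is ~1 in DPD units, hundreds of microns per second);
#' platelet slowing near the coated surface is only visible in the
#' displacement over a time window. This computes per-platelet drift
#' speeds from the last two full snapshots of a run, with periodic x/z
#' displacements unwrapped by minimum image.
#'
#' @param run A `dpd_run` result recorded with `snapshot_every > 0` (at
#'   least two snapshots).
#' @param units Optional [dpd_units()]; when given, `speed` is in m/s.
#' @param n_windows Number of trailing consecutive snapshot pairs to pool
#'   (default 1: the last pair only). Platelet counts fluctuate, so
#'   pooling several windows gives a fuller census.
#' @return data.frame with `id`, `x`, `y`, `z` (positions at the later
#'   snapshot of each window) and `speed` (drift speed over the window).
#' @export
platelet_drift_speeds <- function(run, units = NULL, n_windows = 1) {
  stopifnot(inherits(run, "dpd_run"))
  ns <- length(run$snapshots)
  if (ns < 2) stop("run has fewer than two snapshots", call. = FALSE)
  n_windows <- min(n_windows, ns - 1)
  one <- function(k) {
    s1 <- run$snapshots[[k]]
    s2 <- run$snapshots[[k + 1]]
    window <- (run$snapshot_steps[k + 1] - run$snapshot_steps[k]) * run$dt
    p1 <- s1[s1[, 2] == KIND_PLATELET, , drop = FALSE]
    p2 <- s2[s2[, 2] == KIND_PLATELET, , drop = FALSE]
    common <- intersect(p1[, 1], p2[, 1])
    if (length(common) == 0) return(NULL)
    i1 <- match(common, p1[, 1])
    i2 <- match(common, p2[, 1])
    d <- p2[i2, 3:5, drop = FALSE] - p1[i1, 3:5, drop = FALSE]
    for (ax in c(1, 3)) {
      L <- run$box[ax]
      d[, ax] <- d[, ax] - L * round(d[, ax] / L)
    }
    speed <- sqrt(rowSums(d^2)) / window
    if (!is.null(units)) speed <- speed * units$velocity
    data.frame(id = common,
               x = p2[i2, 3], y = p2[i2, 4], z = p2[i2, 5],
               speed = speed,
               step_from = run$snapshot_steps[k],
               step_to = run$snapshot_steps[k + 1])
  }
  out <- do.call(rbind, lapply(seq(ns - n_windows, ns - 1), one))
  if (is.null(out)) {
    out <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), speed = numeric(),
                      step_from = numeric(), step_to = numeric())
  }
  rownames(out) <- NULL
  out
}
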