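#' @useDynLib thrombodpd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

KIND_LEVELS <- c("plasma", "wall", "coated_surface", "platelet")
KIND_PLASMA <- 0L
KIND_WALL <- 1L
KIND_COATED <- 2L
KIND_PLATELET <- 3L

#' DPD pair-force weight functions
#'
#' Soft-repulsion weights of the standard DPD force field. The
#' conservative force magnitude is `a_ij (1 - r/r_c)` inside the cutoff and
#' zero beyond it; the random weight is `(1 - r/r_c)` and the dissipative
#' weight its square, which is the detailed-balance condition that makes
#' the dissipative/random pair a thermostat at temperature `k_B T` when the
#' noise amplitude is `sqrt(2 gamma k_B T)`.
#'
#' @param r Pair distance(s), DPD length units; must be non-negative.
#' @param a_ij Conservative force coefficient.
#' @param r_c Cutoff radius (default 1).
#' @return Numeric vector of force magnitudes (conservative) or
#'   dimensionless weights (random/dissipative).
#' @export
weight_conservative <- function(r, a_ij, r_c = 1) {
  if (any(r < 0)) stop("pair distance must be non-negative", call. = FALSE)
  ifelse(r < r_c, a_ij * (1 - r / r_c), 0)
}

#' @rdname weight_conservative
#' @export
weight_random <- function(r, r_c = 1) {
  if (any(r < 0)) stop("pair distance must be non-negative", call. = FALSE)
  ifelse(r < r_c, 1 - r / r_c, 0)
}

#' @rdname weight_conservative
#' @export
weight_dissipative <- function(r, r_c = 1) {
  weight_random(r, r_c)^2
}

.expand_pair_matrix <- function(x, name) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(4L, 4L))) stop("'", name, "' must be 4 x 4", call. = FALSE)
    if (max(abs(x - t(x))) > 1e-12) stop("'", name, "' must be symmetric", call. = FALSE)
    return(unname(x))
  }
  stop("'", name, "' must be a 4 x 4 matrix", call. = FALSE)
}

#' Per-kind-pair DPD interaction table
#'
#' Conservative and dissipative coefficients for every ordered pair of
#' particle kinds (plasma, wall, coated surface, platelet), plus the
#' temperature. The random-force amplitude is derived from the
#' fluctuation-dissipation relation `phi = sqrt(2 gamma k_B T)` and is not
#' a free parameter. Defaults follow the calibrated plasma model:
#' a = 25 for fluid-wall pairs and 10 for all other fluid pairs
#' (from a_ij = 75 k_B T / (n_s r_c) with fluid number density 3),
#' gamma = 4.5 throughout, so phi = 3 at k_B T = 1.
#'
#' @param a 4x4 symmetric matrix of conservative coefficients indexed by
#'   kind (plasma, wall, coated_surface, platelet), or `NULL` for defaults.
#' @param gamma 4x4 symmetric matrix of dissipative coefficients, or
#'   `NULL` for the uniform default 4.5.
#' @param kBT Temperature in DPD energy units (default 1).
#' @param r_c Cutoff radius in DPD length units (default 1).
#' @return Object of class `interaction_table` with elements `a`, `gamma`,
#'   `phi`, `kBT`, `r_c`.
#' @export
interaction_table <- function(a = NULL, gamma = NULL, kBT = 1, r_c = 1) {
  if (r_c <= 0) stop("'r_c' must be positive", call. = FALSE)
  if (kBT < 0) stop("'kBT' must be non-negative", call. = FALSE)
  if (is.null(a)) {
    a <- matrix(10, 4, 4)
    a[1, 2] <- a[2, 1] <- 25  # plasma-wall
    a[4, 2] <- a[2, 4] <- 25  # platelet-wall
    a[2, 2] <- a[2, 3] <- a[3, 2] <- a[3, 3] <- 0  # frozen-frozen, unused
  }
  if (is.null(gamma)) gamma <- matrix(4.5, 4, 4)
  a <- .expand_pair_matrix(a, "a")
  gamma <- .expand_pair_matrix(gamma, "gamma")
  if (any(gamma < 0)) stop("dissipative coefficients must be non-negative", call. = FALSE)
  dimnames(a) <- dimnames(gamma) <- list(KIND_LEVELS, KIND_LEVELS)
  structure(
    list(a = a, gamma = gamma, phi = sqrt(2 * gamma * kBT), kBT = kBT, r_c = r_c),
    class = "interaction_table"
  )
}

#' Particle system container
#'
#' Positions, velocities and kinds of every particle, with the simulation
#' box. Walls bound the y axis (specular reflection plus frozen wall
#' particles in slabs of thickness `wall_pad` beyond each face); x and z
#' are periodic. Wall and coated-surface particles are immobile and are
#' never integrated.
#'
#' @param x N x 3 matrix of positions (DPD length units). Mobile particles
#'   must lie inside `[0, Lx) x [0, Ly] x [0, Lz)`; wall particles may sit
#'   within `wall_pad` outside the y faces.
#' @param v N x 3 matrix of velocities; immobile kinds are forced to zero.
#' @param kind Integer vector (0 = plasma, 1 = wall, 2 = coated_surface,
#'   3 = platelet) or character vector of those names.
#' @param box Length-3 extents `c(Lx, Ly, Lz)`.
#' @param wall_pad Thickness of the frozen-wall slabs in y (default 1).
#' @return Object of class `particle_system`.
#' @export
particle_system <- function(x, v = NULL, kind = KIND_PLASMA, box, wall_pad = 1) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("'x' must have three columns", call. = FALSE)
  n <- nrow(x)
  if (is.null(v)) v <- matrix(0, n, 3)
  v <- as.matrix(v)
  if (!all(dim(v) == dim(x))) stop("'v' must match 'x' in shape", call. = FALSE)
  if (is.character(kind)) kind <- match(kind, KIND_LEVELS) - 1L
  kind <- rep_len(as.integer(kind), n)
  if (any(is.na(kind)) || any(kind < 0L | kind > 3L))
    stop("'kind' must be in 0..3 or one of ", paste(KIND_LEVELS, collapse = ", "),
         call. = FALSE)
  if (length(box) != 3 || any(box <= 0))
    stop("'box' must be three positive extents", call. = FALSE)
  immobile <- kind %in% c(KIND_WALL, KIND_COATED)
  v[immobile, ] <- 0
  structure(
    list(x = unname(x), v = unname(v), kind = kind,
         box = as.numeric(box), wall_pad = wall_pad),
    class = "particle_system"
  )
}

#' @export
print.particle_system <- function(x, ...) {
  tab <- table(factor(KIND_LEVELS[x$kind + 1L], levels = KIND_LEVELS))
  cat(sprintf("particle_system: %d particles in %g x %g x %g box\n",
              nrow(x$x), x$box[1], x$box[2], x$box[3]))
  for (k in KIND_LEVELS) if (tab[[k]] > 0) cat(sprintf("  %-14s %d\n", k, tab[[k]]))
  invisible(x)
}

#' Instantaneous kinetic temperature
#'
#' `k_B T` measured from the kinetic energy of mobile particles,
#' `sum(m v^2) / (3 N)`. Used as the thermostat diagnostic for the
#' dissipative/random force pair.
#'
#' @param system A [particle_system()], or an N x 3 velocity matrix.
#' @param mass Particle mass (default 1, the DPD unit).
#' @return Temperature in DPD energy units.
#' @export
kinetic_temperature <- function(system, mass = 1) {
  if (inherits(system, "particle_system")) {
    mob <- system$kind %in% c(KIND_PLASMA, KIND_PLATELET)
    v <- system$v[mob, , drop = FALSE]
  } else {
    v <- as.matrix(system)
  }
  if (nrow(v) == 0) stop("no mobile particles", call. = FALSE)
  mass * sum(v^2) / (3 * nrow(v))
}

# Assemble the parameter list consumed by the compiled engine.
.engine_params <- function(system, table, adhesion = NULL, body_force = 0,
                           dt = 0.01, seed = 1, injection = NULL,
                           max_events = 2e5) {
  if (!inherits(system, "particle_system")) stop("'system' must be a particle_system")
  if (!inherits(table, "interaction_table")) stop("'table' must be an interaction_table")
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  adh_on <- !is.null(adhesion)
  if (!adh_on) {
    adhesion <- adhesion_params(a0 = c(0, 0), gamma_p = c(0, 0),
                                k0 = c(0, 0), F0 = c(1, 1))
  }
  stopifnot(inherits(adhesion, "adhesion_params"))
  inj <- list(rate = 0, inlet_len = 2, outlet_len = -1, margin = 0.5,
              diameter = 0.6, max_new = 0)
  if (!is.null(injection)) inj[names(injection)] <- injection
  list(
    box = system$box,
    wall_pad = system$wall_pad,
    r_c = table$r_c,
    a = table$a,
    gamma = table$gamma,
    kBT = table$kBT,
    body_force = body_force,
    dt = dt,
    adhesion_on = adh_on,
    a0 = adhesion$a0,
    gamma_p = adhesion$gamma_p,
    k0 = adhesion$k0,
    F0 = adhesion$F0,
    a1 = adhesion$a1,
    r_a = adhesion$r_a,
    t_stage2 = adhesion$t_stage2,
    p_dis_override = if (is.na(adhesion$p_dis_override)) -1 else adhesion$p_dis_override,
    bond_additive = isTRUE(adhesion$bond_additive),
    f_projection = isTRUE(adhesion$f_projection),
    inject_rate = inj$rate,
    inlet_len = inj$inlet_len,
    outlet_len = inj$outlet_len,
    inject_margin = inj$margin,
    platelet_diameter = inj$diameter,
    max_new_platelets = as.integer(inj$max_new),
    seed = as.double(seed),
    max_events = as.double(max_events)
  )
}

#' Compute DPD forces for a configuration
#'
#' One-shot evaluation of the total per-particle force (conservative +
#' dissipative + random + body force, and viscoelastic bond forces for
#' bonded pairs) for a frozen configuration. Mainly a testing and
#' diagnostic surface; the integrator evaluates forces internally.
#'
#' @param system A [particle_system()].
#' @param table An [interaction_table()].
#' @param dt Timestep used to scale the random force (default 0.01).
#' @param seed,step Seed and step index keying the counter-based noise;
#'   fixed values reproduce the identical random forces.
#' @param body_force Constant force along x applied to mobile particles.
#' @param adhesion Optional [adhesion_params()]; with `bonds` supplies
#'   pre-existing bonds as a matrix with columns (a, b, class, stage,
#'   t_form), 1-based particle ids, class 0 = platelet-platelet,
#'   1 = platelet-coated.
#' @param bonds Optional bond matrix (see above).
#' @return List with `force` (N x 3), `nonbond_force` (N x 3; the DPD and
#'   body-force part acting on platelets, which drives detachment
#'   kinetics) and `n_coincident` (count of zero-distance pairs).
#' @export
dpd_forces <- function(system, table, dt = 0.01, seed = 1, step = 0,
                       body_force = 0, adhesion = NULL, bonds = NULL) {
  par <- .engine_params(system, table, adhesion = adhesion,
                        body_force = body_force, dt = dt, seed = seed)
  par$bonds0 <- bonds
  dpd_forces_cpp(system$x, system$v, system$kind, par, step)
}

#' Reference all-pairs DPD force computation
#'
#' Direct O(n^2) evaluation of the conservative and dissipative DPD
#' forces in plain R, with the random term omitted (theta = 0). Serves as
#' an independent oracle for the compiled engine on small systems.
#'
#' @inheritParams dpd_forces
#' @return N x 3 matrix of forces.
#' @export
dpd_pair_forces_ref <- function(system, table) {
  x <- system$x; v <- system$v; kind <- system$kind
  n <- nrow(x)
  box <- system$box
  f <- matrix(0, n, 3)
  mobile <- kind %in% c(KIND_PLASMA, KIND_PLATELET)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!mobile[i] && !mobile[j]) next
      d <- x[i, ] - x[j, ]
      # periodic x, z
      for (ax in c(1, 3)) {
        if (d[ax] > box[ax] / 2) d[ax] <- d[ax] - box[ax]
        if (d[ax] < -box[ax] / 2) d[ax] <- d[ax] + box[ax]
      }
      r <- sqrt(sum(d^2))
      if (r >= table$r_c) next
      e <- if (r < 1e-12) c(1, 0, 0) else d / r
      w <- 1 - r / table$r_c
      ki <- kind[i] + 1L; kj <- kind[j] + 1L
      fc <- table$a[ki, kj] * w
      fd <- -table$gamma[ki, kj] * w^2 * sum(e * (v[i, ] - v[j, ]))
      fij <- (fc + fd) * e
      f[i, ] <- f[i, ] + fij
      f[j, ] <- f[j, ] - fij
    }
  }
  f
}

#' Integrate a particle system
#'
#' Advance a [particle_system()] by `n_steps` of the modified
#' velocity-Verlet scheme (dissipative forces evaluated at the half-step
#' velocity, lambda = 1/2), with periodic x/z boundaries, specular y-wall
#' reflection, optional viscoelastic adhesion bonds with stochastic
#' attach/detach, platelet injection at the inlet and evaporation at the
#' outlet. All noise derives from `seed` through counter-based hashing,
#' so repeated calls are bit-identical.
#'
#' @inheritParams dpd_forces
#' @param n_steps Number of timesteps.
#' @param injection Optional list with elements `rate` (platelets per DPD
#'   time), `inlet_len`, `outlet_len` (x-extents of the inlet/outlet
#'   slabs; `outlet_len = -1` disables evaporation), `margin` (minimum
#'   initial y distance from the walls), `diameter` (platelet diameter)
#'   and `max_new` (capacity for injected platelets).
#' @param metrics_every Record counts/temperature and the adhered-platelet
#'   snapshot every this many steps (0 = off).
#' @param snapshot_every Record full-system snapshots every this many
#'   steps (0 = off).
#' @param profile Optional list `list(bins =, start_step =, every =)`
#'   accumulating the plasma x-velocity profile across y.
#' @param step0,t0 Global step index and DPD time at entry (for chained
#'   runs).
#' @return A list of class `dpd_run` (final state, bonds, metrics,
#'   snapshots, profile accumulators, bond event log).
#' @export
dpd_run <- function(system, table, n_steps, dt = 0.01, seed = 1,
                    body_force = 0, adhesion = NULL, bonds = NULL,
                    injection = NULL, metrics_every = 0L,
                    snapshot_every = 0L, profile = NULL,
                    step0 = 0, t0 = 0) {
  par <- .engine_params(system, table, adhesion = adhesion,
                        body_force = body_force, dt = dt, seed = seed,
                        injection = injection)
  par$bonds0 <- bonds
  control <- list(
    n_steps = as.double(n_steps), step0 = as.double(step0), t0 = as.double(t0),
    metrics_every = as.integer(metrics_every),
    snapshot_every = as.integer(snapshot_every),
    profile_bins = if (is.null(profile)) 0L else as.integer(profile$bins),
    profile_start_step = if (is.null(profile)) 0 else as.double(profile$start_step),
    profile_every = if (is.null(profile)) 0L else as.integer(profile$every %||% 1L)
  )
  out <- dpd_run_cpp(system$x, system$v, system$kind, par, control)
  if (out$n_coincident > 0)
    warning(sprintf("%d coincident particle pair(s); substituted +x direction",
                    as.integer(out$n_coincident)), call. = FALSE)
  out$system <- particle_system(out$x, out$v, out$kind, system$box,
                                wall_pad = system$wall_pad)
  out$dt <- dt
  out$box <- system$box
  class(out) <- "dpd_run"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
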