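#' Coated-microchannel specification
#'
#' Geometry and seeding densities for the simulated microchannel: a
#' rectangular box, periodic in x (flow) and z (span), bounded in y by
#' frozen-particle walls, with the innermost bottom wall layer tagged as
#' the protein-coated surface. The default 80 x 20 x 40 box corresponds
#' to a 400 x 100 x 200 micron channel section at the 5 micron length
#' unit.
#'
#' @param Lx,Ly,Lz Channel extents in DPD length units (defaults
#'   80 x 20 x 40).
#' @param fluid_density Plasma number density (default 3).
#' @param wall_density Wall-particle number density (default 7.5).
#' @param coating One of `"collagen"`, `"vwf"`, `"generic"` — which
#'   protein the floor is coated with (a label; the force parameters come
#'   from [dpd_preset()]).
#' @param wall_layer_thickness Thickness of the frozen-wall slabs
#'   (default 1 cutoff radius).
#' @param platelet_diameter Platelet diameter in DPD length units
#'   (default 0.6, i.e. 3 microns).
#' @param injection_rate Platelets injected per DPD time unit, or `NULL`
#'   to derive one at run time from `free_platelet_density` and the mean
#'   flow.
#' @param free_platelet_density Target free-stream platelet number density
#'   used when `injection_rate` is `NULL` (default 0.002 per cubic length
#'   unit).
#' @param inlet_length,outlet_length x-extents of the injection slab and
#'   of the outlet (evaporation) region (default 2 each).
#' @param min_separation Minimum plasma-plasma distance enforced during
#'   seeding by rejection (default 0.2; soft DPD potentials tolerate
#'   moderate initial overlap).
#' @return Object of class `channel_spec`.
#' @export
channel_spec <- function(Lx = 80, Ly = 20, Lz = 40,
                         fluid_density = 3, wall_density = 7.5,
                         coating = c("collagen", "vwf", "generic"),
                         wall_layer_thickness = 1,
                         platelet_diameter = 0.6,
                         injection_rate = NULL,
                         free_platelet_density = 0.002,
                         inlet_length = 2, outlet_length = 2,
                         min_separation = 0.2) {
  coating <- match.arg(coating)
  if (any(c(Lx, Ly, Lz) <= 0)) stop("channel extents must be positive", call. = FALSE)
  if (fluid_density <= 0 || wall_density <= 0)
    stop("densities must be positive", call. = FALSE)
  if (inlet_length + outlet_length >= Lx)
    stop("inlet and outlet slabs must be disjoint and inside the channel",
         call. = FALSE)
  structure(
    list(Lx = Lx, Ly = Ly, Lz = Lz,
         fluid_density = fluid_density, wall_density = wall_density,
         coating = coating, wall_layer_thickness = wall_layer_thickness,
         platelet_diameter = platelet_diameter,
         injection_rate = injection_rate,
         free_platelet_density = free_platelet_density,
         inlet_length = inlet_length, outlet_length = outlet_length,
         min_separation = min_separation),
    class = "channel_spec"
  )
}

# simple-cubic wall lattice filling a slab; returns matrix of positions
.wall_slab <- function(Lx, Lz, y_lo, y_hi, density) {
  h <- density^(-1 / 3)
  nx <- max(1L, round(Lx / h))
  nz <- max(1L, round(Lz / h))
  ny <- max(1L, round((y_hi - y_lo) / h))
  xs <- (seq_len(nx) - 0.5) * (Lx / nx)
  zs <- (seq_len(nz) - 0.5) * (Lz / nz)
  ys <- y_lo + (seq_len(ny) - 0.5) * ((y_hi - y_lo) / ny)
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, c("x", "y", "z")])
}

# uniform plasma seeding with cell-hash min-separation rejection
.seed_plasma <- function(n, Lx, Ly, Lz, min_sep, max_tries = 50L) {
  pos <- matrix(NA_real_, n, 3)
  if (min_sep <= 0) {
    pos[, 1] <- stats::runif(n, 0, Lx)
    pos[, 2] <- stats::runif(n, 0, Ly)
    pos[, 3] <- stats::runif(n, 0, Lz)
    return(pos)
  }
  cs <- min_sep
  ncx <- max(1L, floor(Lx / cs)); ncy <- max(1L, floor(Ly / cs))
  ncz <- max(1L, floor(Lz / cs))
  grid <- new.env(hash = TRUE, size = n)
  key <- function(cx, cy, cz) paste(cx, cy, cz)
  ms2 <- min_sep^2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- c(stats::runif(1, 0, Lx), stats::runif(1, 0, Ly), stats::runif(1, 0, Lz))
      cx <- min(floor(p[1] / Lx * ncx), ncx - 1)
      cy <- min(floor(p[2] / Ly * ncy), ncy - 1)
      cz <- min(floor(p[3] / Lz * ncz), ncz - 1)
      clash <- FALSE
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        ids <- grid[[key((cx + dx) %% ncx, cy + dy, (cz + dz) %% ncz)]]
        if (is.null(ids)) next
        for (j in ids) {
          d <- p - pos[j, ]
          if (d[1] > Lx / 2) d[1] <- d[1] - Lx else if (d[1] < -Lx / 2) d[1] <- d[1] + Lx
          if (d[3] > Lz / 2) d[3] <- d[3] - Lz else if (d[3] < -Lz / 2) d[3] <- d[3] + Lz
          if (sum(d^2) < ms2) { clash <- TRUE; break }
        }
        if (clash) break
      }
      if (!clash) {
        pos[i, ] <- p
        k <- key(cx, cy, cz)
        grid[[k]] <- c(grid[[k]], i)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      # dense corner: accept the last draw rather than fail (soft potentials)
      pos[i, ] <- p
    }
  }
  pos
}

#' Build the coated-channel particle system
#'
#' Populates the frozen wall slabs on both y faces at the wall density on
#' a simple-cubic lattice, tags the innermost bottom layer as the coated
#' surface, fills the interior with plasma at the fluid density (uniform
#' random with min-separation rejection), and samples plasma velocities
#' from the Maxwell distribution at `kBT` with the net drift removed.
#'
#' @param spec A [channel_spec()].
#' @param seed Integer seed for the initial configuration.
#' @param kBT Temperature for the initial velocities (default 1).
#' @return A [particle_system()].
#' @examples
#' sys <- build_channel(channel_spec(Lx = 10, Ly = 10, Lz = 10), seed = 1)
#' sys
#' @export
build_channel <- function(spec, seed = 1, kBT = 1) {
  stopifnot(inherits(spec, "channel_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  wt <- spec$wall_layer_thickness
  bottom <- .wall_slab(spec$Lx, spec$Lz, -wt, 0, spec$wall_density)
  top <- .wall_slab(spec$Lx, spec$Lz, spec$Ly, spec$Ly + wt, spec$wall_density)
  # innermost bottom layer (largest y among bottom layers) is the coating
  ylayers <- sort(unique(bottom[, 2]), decreasing = TRUE)
  coated <- bottom[, 2] == ylayers[1]
  wall_kind <- c(ifelse(coated, KIND_COATED, KIND_WALL),
                 rep(KIND_WALL, nrow(top)))

  n_plasma <- round(spec$fluid_density * spec$Lx * spec$Ly * spec$Lz)
  plasma <- .seed_plasma(n_plasma, spec$Lx, spec$Ly, spec$Lz, spec$min_separation)

  x <- rbind(plasma, bottom, top)
  kind <- c(rep(KIND_PLASMA, n_plasma), as.integer(wall_kind))
  v <- matrix(0, nrow(x), 3)
  vp <- matrix(stats::rnorm(3 * n_plasma, sd = sqrt(kBT)), n_plasma, 3)
  vp <- sweep(vp, 2, colMeans(vp))  # remove net drift
  v[seq_len(n_plasma), ] <- vp

  particle_system(x, v, kind, box = c(spec$Lx, spec$Ly, spec$Lz), wall_pad = wt)
}

#' Table-derived parameter presets
#'
#' Named bundles of DPD interaction and adhesion parameters for the
#' coated-surface simulations. Coefficients are ordered
#' (platelet-platelet, platelet-coated-surface).
#'
#' * `collagen` — multilayer aggregation: a0 = (50, 400),
#'   gamma_p = (4.5, 80), k0 = (120, 120).
#' * `vwf_table1` — VWF parameter set with a0 = (150, 400),
#'   gamma_p = (80, 80), k0 = (10, 80).
#' * `vwf_fig7` — alternative VWF set used for the monolayer morphology
#'   snapshots: a0 = (50, 400), gamma_p = (80, 80), k0 = (120, 120).
#' * `generic_fig2` — base set for the stochastic-parameter sweeps:
#'   a0 = (80, 400), gamma_p = (4.5, 80), k0 = (120, 120).
#'
#' All presets share F0 = 1000, a1 = 1200, r_a = 2/3 and the stage-2
#' promotion time of 300 DPD time units.
#'
#' @param name Preset name.
#' @return List with elements `name`, `interaction`
#'   (an [interaction_table()]) and `adhesion` (an [adhesion_params()]).
#' @export
dpd_preset <- function(name = c("collagen", "vwf_table1", "vwf_fig7",
                                "generic_fig2")) {
  name <- match.arg(name)
  adh <- switch(name,
    collagen = adhesion_params(a0 = c(50, 400), gamma_p = c(4.5, 80),
                               k0 = c(120, 120)),
    vwf_table1 = adhesion_params(a0 = c(150, 400), gamma_p = c(80, 80),
                                 k0 = c(10, 80)),
    vwf_fig7 = adhesion_params(a0 = c(50, 400), gamma_p = c(80, 80),
                               k0 = c(120, 120)),
    generic_fig2 = adhesion_params(a0 = c(80, 400), gamma_p = c(4.5, 80),
                                   k0 = c(120, 120))
  )
  list(name = name, interaction = interaction_table(), adhesion = adh)
}

#' @rdname dpd_preset
#' @export
dpd_presets <- function() c("collagen", "vwf_table1", "vwf_fig7", "generic_fig2")
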