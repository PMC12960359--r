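#' Viscoelastic bond parameters
#'
#' Spring-dashpot coefficients of a platelet adhesion bond. The elastic
#' term is a linear spring `a_p (1 - r/r_c)` along the bond axis that is
#' attractive (`a_p = -a0`) between the switch radius `r_a` and the cutoff
#' `r_c`, and strongly repulsive (`a_p = a1`) below `r_a` to prevent
#' particle overlap. The dashpot opposes relative motion along the bond
#' with coefficient `gamma_p` weighted by `(1 - r/r_c)^2`.
#'
#' @param a0 Attraction coefficient (DPD force units).
#' @param gamma_p Bond damping coefficient.
#' @param a1 Overlap repulsion coefficient (default 1200, used for every
#'   bond class).
#' @param r_c Cutoff radius (default 1).
#' @param r_a Inner switch radius; defaults to `2 r_c / 3`.
#' @return Object of class `visco_params`.
#' @export
visco_params <- function(a0, gamma_p, a1 = 1200, r_c = 1, r_a = 2 * r_c / 3) {
  if (a0 < 0 || a1 < 0 || gamma_p < 0)
    stop("bond coefficients must be non-negative", call. = FALSE)
  if (!(r_a > 0 && r_a < r_c))
    stop("'r_a' must satisfy 0 < r_a < r_c", call. = FALSE)
  structure(list(a0 = a0, gamma_p = gamma_p, a1 = a1, r_a = r_a, r_c = r_c),
            class = "visco_params")
}

#' Stochastic bond kinetics parameters
#'
#' Bell-type force-dependent detachment: a bond under load F ruptures at
#' rate `k(F) = k0 exp(F/F0)`, giving per-window rupture probability
#' `P_dis = 1 - exp(-k(F) dt)`.
#'
#' @param k0 Zero-force detachment rate (1 / DPD time).
#' @param F0 Characteristic bond force (DPD force units).
#' @param dt Probability window (DPD time, default 0.01 = one timestep).
#' @return Object of class `stoch_params`.
#' @export
stoch_params <- function(k0, F0 = 1000, dt = 0.01) {
  if (k0 < 0) stop("'k0' must be non-negative", call. = FALSE)
  if (F0 <= 0) stop("'F0' must be positive", call. = FALSE)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  structure(list(k0 = k0, F0 = F0, dt = dt), class = "stoch_params")
}

#' Elastic (spring) bond force
#'
#' Signed force magnitude along the bond unit vector e_ij (pointing from
#' the partner to the particle): negative values pull the pair together
#' (attraction), positive values push apart. Zero beyond the cutoff.
#'
#' @param r Pair distance(s), DPD length units.
#' @param params A [visco_params()].
#' @return Signed force magnitude(s).
#' @examples
#' p <- visco_params(a0 = 400, gamma_p = 80)
#' elastic_bond_force(5 / 6, p)   # attractive, about -66.7
#' @export
elastic_bond_force <- function(r, params) {
  stopifnot(inherits(params, "visco_params"))
  if (any(r < 0)) stop("pair distance must be non-negative", call. = FALSE)
  ap <- ifelse(r <= params$r_a, params$a1, -params$a0)
  ifelse(r < params$r_c, ap * (1 - r / params$r_c), 0)
}

#' Viscous (dashpot) bond force
#'
#' Signed force magnitude `-gamma_p (1 - r/r_c)^2 (e . v)` opposing
#' relative motion along the bond axis; zero beyond the cutoff.
#'
#' @param r Pair distance(s).
#' @param rel_velocity Relative velocity projected on the bond axis,
#'   `e_ij . v_ij` (positive = separating).
#' @param params A [visco_params()].
#' @return Signed force magnitude(s).
#' @export
viscous_bond_force <- function(r, rel_velocity, params) {
  stopifnot(inherits(params, "visco_params"))
  if (any(r < 0)) stop("pair distance must be non-negative", call. = FALSE)
  f <- -params$gamma_p * (1 - r / params$r_c)^2 * rel_velocity
  f[rep_len(r >= params$r_c, length(f))] <- 0
  f
}

#' Force-dependent detachment rate and probability
#'
#' `detachment_rate()` evaluates the Bell rate `k0 exp(F/F0)`; the
#' zero-force branch is its continuous limit (the exponential is
#' short-circuited for `F/F0 < 1e-3`, where it is 1 to within 0.1%).
#' `detachment_probability()` converts the rate into the probability that
#' the bond ruptures within a window `dt`, `1 - exp(-k(F) dt)`.
#'
#' @param F Applied force magnitude(s), DPD force units; non-negative.
#' @param params A [stoch_params()].
#' @param dt Probability window; defaults to `params$dt`.
#' @return Rate (1 / DPD time) or probability in `[0, 1]`.
#' @examples
#' s <- stoch_params(k0 = 100, F0 = 1000)
#' detachment_probability(0, s)   # 1 - exp(-1) ~ 0.632
#' @export
detachment_rate <- function(F, params) {
  stopifnot(inherits(params, "stoch_params"))
  if (any(F < 0)) stop("force must be non-negative", call. = FALSE)
  ratio <- F / params$F0
  ifelse(ratio < 1e-3, params$k0, params$k0 * exp(pmin(ratio, 700)))
}

#' @rdname detachment_rate
#' @export
detachment_probability <- function(F, params, dt = params$dt) {
  if (any(dt <= 0)) stop("'dt' must be positive", call. = FALSE)
  p <- 1 - exp(-detachment_rate(F, params) * dt)
  pmin(pmax(p, 0), 1)
}

#' Adhesion model parameter bundle
#'
#' All adhesion parameters for the two bond classes, ordered
#' (platelet-platelet, platelet-coated-surface). Bond maturation: stage-1
#' (reversible) bonds older than `t_stage2` are promoted to stage 2
#' (irreversible, fibrin-enhanced) and are never removed by the
#' stochastic sweep.
#'
#' @param a0 Length-2 attraction coefficients (pp, ps).
#' @param gamma_p Length-2 bond damping coefficients.
#' @param k0 Length-2 zero-force detachment rates.
#' @param F0 Length-2 characteristic bond forces (default 1000 for both).
#' @param a1 Overlap repulsion coefficient (default 1200).
#' @param r_a Inner switch radius (default 2/3).
#' @param t_stage2 Age (DPD time) at which bonds become irreversible
#'   (default 300).
#' @param p_dis_override If not `NA`, fixes the detachment probability to
#'   this value for every pair (testing hook).
#' @param bond_additive If `TRUE`, bond forces add on top of the DPD
#'   conservative/dissipative pair force; the default replaces those two
#'   terms for bonded pairs (the random term is always retained).
#' @param f_projection If `TRUE`, the detachment force is the projection
#'   of the non-bond force onto the bond axis instead of its magnitude.
#' @return Object of class `adhesion_params`.
#' @export
adhesion_params <- function(a0, gamma_p, k0, F0 = c(1000, 1000), a1 = 1200,
                            r_a = 2 / 3, t_stage2 = 300,
                            p_dis_override = NA_real_,
                            bond_additive = FALSE, f_projection = FALSE) {
  len2 <- function(x, name) {
    x <- rep_len(as.numeric(x), 2L)
    if (any(!is.finite(x)) || any(x < 0))
      stop("'", name, "' must be non-negative", call. = FALSE)
    x
  }
  F0 <- rep_len(as.numeric(F0), 2L)
  if (any(F0 <= 0)) stop("'F0' must be positive", call. = FALSE)
  structure(
    list(a0 = len2(a0, "a0"), gamma_p = len2(gamma_p, "gamma_p"),
         k0 = len2(k0, "k0"), F0 = F0, a1 = a1, r_a = r_a,
         t_stage2 = t_stage2, p_dis_override = p_dis_override,
         bond_additive = bond_additive, f_projection = f_projection),
    class = "adhesion_params"
  )
}

#' Reference stochastic attach/detach sweep
#'
#' Plain-R implementation of one stochastic bond update over explicit
#' candidate pairs, used as an enumeration oracle for the compiled
#' engine's sweep. Rules: per candidate pair a uniform draw `P_r` is
#' compared against `P_dis(F)`; an unbonded pair forms a bond when
#' `P_r >= P_dis` (formation requires a recruiter: the coated surface, or
#' a platelet already adhered at sweep start); a stage-1 bond is removed
#' when `P_r < P_dis`; stage-2 bonds are never touched.
#'
#' @param pairs data.frame with columns `a`, `b` (particle ids, a < b) and
#'   `class` (0 platelet-platelet, 1 platelet-coated).
#' @param bonded Logical vector: is the pair currently bonded?
#' @param stage Integer vector of bond stages (ignored where unbonded).
#' @param p_dis Numeric vector of detachment probabilities per pair.
#' @param p_r Numeric vector of uniform draws per pair.
#' @param adhered_a,adhered_b Logical: is the a/b member a recruiter
#'   (adhered platelet or coated particle) at sweep start?
#' @return Logical vector: bonded after the sweep.
#' @export
bond_sweep_ref <- function(pairs, bonded, stage, p_dis, p_r,
                           adhered_a, adhered_b) {
  out <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (bonded[i]) {
      if (stage[i] >= 2) out[i] <- TRUE
      else out[i] <- !(p_r[i] < p_dis[i])
    } else {
      recruiter <- if (pairs$class[i] == 1) TRUE else (adhered_a[i] || adhered_b[i])
      out[i] <- recruiter && p_r[i] >= p_dis[i]
    }
  }
  out
}
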