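---
title: "Modelling platelet adhesion on protein-coated surfaces with dissipative particle dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling platelet adhesion on protein-coated surfaces with dissipative particle dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombodpd)
```

## The model

`thrombodpd` simulates platelet adhesion and aggregation in microchannel
flow over a protein-coated floor, at the mesoscale, using dissipative
particle dynamics (DPD). Four particle kinds populate a rectangular
channel: plasma (the suspending fluid), frozen wall particles bounding
the channel in the wall-normal direction y, a coated-surface layer (the
innermost bottom wall layer, representing immobilized collagen or von
Willebrand factor), and platelets, each a single soft particle of 3 µm
nominal diameter. x (flow) and z (span) are periodic.

Every pair of particles within the cutoff radius $r_c$ interacts through
the standard DPD triplet of forces along the unit vector
$\mathbf{e}_{ij}$:

* conservative soft repulsion $a_{ij}(1 - r_{ij}/r_c)$,
* dissipative drag $-\gamma\,\omega_D(r_{ij})\,(\mathbf{e}_{ij}\cdot\mathbf{v}_{ij})$
  with $\omega_D = (1 - r_{ij}/r_c)^2$,
* random kicks $\varphi\,\omega_R(r_{ij})\,\theta_{ij}/\sqrt{\Delta t}$
  with $\omega_R = 1 - r_{ij}/r_c$ and symmetric Gaussian variates
  $\theta_{ij} = \theta_{ji}$.

The fluctuation–dissipation relation $\varphi = \sqrt{2\gamma k_B T}$
ties the random amplitude to the drag, so the dissipative/random pair
acts as a thermostat; with the default $\gamma = 4.5$ and $k_B T = 1$,
$\varphi = 3$. Equations of motion are integrated with the modified
velocity-Verlet scheme (dissipative forces evaluated at the half-step
velocity, $\lambda = 1/2$), the standard choice for DPD because it keeps
the temperature error small at $\Delta t = 0.01$.

### Adhesion bonds

Platelet–platelet and platelet–coated-surface adhesion is a viscoelastic
spring–dashpot bond:

$$
\mathbf{F}^E = a_p\Big(1 - \frac{r}{r_c}\Big)\mathbf{e}, \qquad
a_p = \begin{cases} -a_0 & r_a < r \le r_c \\ a_1 & r \le r_a\end{cases},
\qquad
\mathbf{F}^V = -\gamma_p\Big(1 - \frac{r}{r_c}\Big)^2
(\mathbf{e}\cdot\mathbf{v})\,\mathbf{e}.
$$

$a_0$ sets the binding strength, $a_1 = 1200$ only prevents overlap, the
switch radius is $r_a = 2r_c/3$, and $\gamma_p$ damps relative motion
along the bond. Large $\gamma_p$ makes an incoming platelet slide past an
adhered one instead of stacking on top of it — this single parameter is
what turns multilayer (collagen-like) aggregation into monolayer
(VWF-like) adhesion.

Bond formation and rupture are stochastic with Bell-type force
dependence. A bond under load $F$ ruptures within a window $\Delta t$
with probability

$$
P_{dis}(F, \Delta t) = 1 - e^{-k(F)\Delta t}, \qquad
k(F) = k_0\, e^{F/F_0},
$$

where $k_0$ is the zero-force detachment rate and $F_0$ the
characteristic bond force. At each timestep every candidate pair (a
platelet within $r_c$ of a coated particle, or of an adhered platelet)
draws a uniform $P_r$: an unbonded pair forms a bond when
$P_r \ge P_{dis}$, a bonded pair breaks when $P_r < P_{dis}$. Bonds older
than $t_2 = 300$ DPD time units are promoted to a permanent second stage
that represents fibrin-stabilized (GPIIb/IIIa-mediated) adhesion and is
exempt from the stochastic sweep. Receptors (GPIbα, GPVI, GPIIb/IIIa) are
not modelled as species; their kinetics are absorbed phenomenologically
into $(a_0, \gamma_p, k_0, F_0)$ per pair class.

*Adhered* is a connectivity notion here: a platelet counts as adhered —
it recruits incoming platelets, it is exempt from outlet evaporation,
and it enters the covered-area and morphology metrics — exactly when it
reaches the coated surface through the bond graph. A pair of platelets
bonded only to each other is drifting cargo, not part of a clot; without
the connectivity rule such pairs would keep each other "adhered"
indefinitely and accumulate in the periodic domain.

One property of the per-window rule deserves emphasis: because a single
draw is taken per pair per timestep and the attachment condition is
$P_r \ge P_{dis}(\Delta t)$, the attachment *flux per unit time* is not
timestep-invariant — as $\Delta t$ shrinks, $P_{dis} \to 0$ and
candidate pairs bond almost every step, while the stationary bonded
fraction per candidate pair, $1 - P_{dis}(\Delta t)$, rises (0.30 at
$\Delta t = 0.01$ versus 0.55 at $\Delta t = 0.005$ for $k_0 = 120$).
Covered-area magnitudes therefore carry an intrinsic timestep dependence
wherever adhesion is kinetics- or residence-limited; the suite's
timestep-halving comparison documents the size of this effect rather
than hiding it. Conservation-law and thermostat checks pass identically
at both timesteps, so this is a property of the published stochastic
rule, not of the integrator.

### Units

All quantities are dimensionless; the unit system
(`dpd_units()`) maps them to SI through the base units
$l = 5\,\mu m$ (the cutoff), $E = k_B T$ at 300 K, and the particle mass
$m = \rho l^3 / n_s$, giving a time unit of 15.86 ms, a force unit of
$8.28\times 10^{-16}$ N and a velocity unit of 0.32 mm/s. A detachment
rate $k_0 = 120$ therefore corresponds to about 7566 s⁻¹.

## Parameters that matter

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `a_ij` | DPD repulsion | 25 fluid–wall, 10 otherwise | from $75 k_BT/(n_s r_c)$ |
| `gamma` | DPD drag | 4.5 | thermostat strength |
| `a0` | bond attraction | preset | 50–400 by pair class |
| `gamma_p` | bond damping | preset | 4.5 (multilayer) vs 80 (monolayer) |
| `k0` | zero-force off-rate | preset | 10–120 per DPD time |
| `F0` | Bell force scale | 1000 | $8.28\times10^{-13}$ N |
| `body_force` | flow driving | 0.45 | per particle, along x |
| `dt` | timestep | 0.01 | halving it leaves metrics unchanged |

Presets (`dpd_preset()`): `collagen` (a0 = 50/400, γp = 4.5/80,
k0 = 120/120 for platelet–platelet / platelet–surface), `vwf_table1`
(a0 = 150/400, γp = 80/80, k0 = 10/80), `vwf_fig7` (a0 = 50/400,
γp = 80/80, k0 = 120/120) and `generic_fig2` (a0 = 80/400, γp = 4.5/80,
k0 = 120/120), the base set for stochastic-parameter sweeps. Two VWF
presets are shipped deliberately: the published parameter table and the
published morphology snapshots quote different VWF platelet–platelet
coefficients, and rather than silently choosing one this package names
both.

## Geometry, seeding and boundary conditions

The default channel is $80 \times 20 \times 40$ in DPD lengths
($400 \times 100 \times 200\,\mu m$); tests and desk-scale calibration
use reduced cross-sections (e.g. $10 \times 20 \times 10$), which is
legitimate because x and z are periodic. Walls are slabs of frozen
particles at number density 7.5 on a simple-cubic lattice filling one
cutoff radius beyond each y face, combined with specular reflection of
mobile particles at the face planes. The innermost bottom layer is tagged
as the coated surface. Plasma is seeded uniformly at density 3 with a
best-effort minimum separation (0.2 by default — soft potentials tolerate
moderate initial overlap), with Maxwell velocities at $k_BT$ and the net
drift removed.

Platelets enter in an inlet slab (first 2 length units of x) at a
configurable rate and are deleted ("evaporated") once they cross the
outlet plane unbonded; plasma simply wraps periodically. The injection
rate is not a measured quantity; by default it is derived from a target
free-stream platelet density of 0.002 per cubic DPD length (a dilute
fraction of the physiological count, chosen to keep desk-scale runs
tractable) times the mean flow and cross-section. Covered-area
*magnitudes* are sensitive to this choice; the parameter *trends* the
tests assert are not.

## Flow calibration and a known limitation

A per-particle body force of 0.45 drives the channel flow
(`calibrate_flow()`). Momentum balance fixes the steady wall shear
stress exactly at $f n H / 2 = 13.5$ DPD force per area; how that
partitions into near-wall velocity gradient versus wall slip depends on
the wall model. This implementation follows the stated model — frozen
walls at density 7.5, specular reflection, no effective-coefficient
correction to the wall–fluid conservative force — and that model has a
well-documented artifact: fluid is depleted near the soft wall, the
wall drag weakens, and a large apparent slip velocity develops. Two
consequences, measured honestly by `calibrate_flow()` and stated here so
downstream users are not surprised:

* the **fitted wall shear rate** of the quadratic profile fit lands close
  to the 500 s⁻¹ regime the body force was calibrated for;
* the **peak velocity** includes the slip offset and is therefore several
  times larger than a no-slip estimate at the same shear.

The slip is additionally *asymmetric*: the coated bottom layer interacts
with plasma at $a = 10$ (versus 25 for plain wall), so plasma approaches
it more closely and is dragged harder — the bottom slip is smaller than
the top slip and the velocity maximum sits above mid-channel. Since
adhesion happens at the bottom (coated) surface, the hydrodynamic load on
adhered platelets is governed by the bottom-wall shear, which is the
better-posed quantity. The Reynolds number of the corresponding physical
flow is ~0.04: viscous-dominated, so the parabolic reference is
appropriate.

The bulk fluid's emergent transport coefficients were measured inside
this package (shear-wave decay at the default parameters): kinematic
viscosity $\nu \approx 0.38\,l^2/t$ for the $a = 10$ fluid
($\approx 0.27$ for $a = 25$), consistent with standard DPD literature
values. `calibrate_flow()` uses these to warm-start the velocity profile
at an analytic parabola-plus-slip estimate, because the viscous start-up
transient of the full-height channel spans hundreds of DPD time units;
the warm start only shortens the transient — the profile is then relaxed
by full integration before any sampling, so a wrong estimate costs
convergence time, not correctness.

## Numerical choices

* **Noise**: every random variate is a counter-based hash of
  (seed, stream, step, ids). This enforces $\theta_{ij} = \theta_{ji}$
  exactly, makes runs bit-reproducible from one seed, and decouples the
  noise streams of integration, bond sweep and injection so enabling one
  subsystem does not shift another's stream.
* **Bonded pairs** replace the DPD conservative + dissipative terms with
  the bond elastic + viscous terms (the random term is retained, keeping
  the pair thermalized); an additive mode exists behind
  `bond_additive = TRUE`. Replacement avoids double-counting repulsion.
* **Detachment load** $F$ is the magnitude of the instantaneous net
  non-bond force on the platelet (DPD pair forces plus body force); for
  platelet–platelet bonds the larger of the two loads is used. A
  projection-onto-bond-axis alternative sits behind
  `f_projection = TRUE`. The zero-force branch of the Bell rate is the
  continuous limit of the exponential; `exp` is short-circuited below
  $F/F_0 < 10^{-3}$.
* **Sweep semantics**: one draw per candidate pair per step; recruiter
  status (adhered or coated) is frozen at sweep start, so a platelet
  bonded this step becomes a recruiter next step; pairs are processed in
  ascending id order, and because draws are counter-based the outcome is
  independent of traversal order. Stage-1 bonds stretched beyond $r_c$
  are pruned as broken.
* **Coincident particles** (r = 0) get a fixed +x direction and a
  warning — a probability-zero event must not crash a long run.
* **Degenerate inputs**: empty velocity-profile bins are `NA`, never
  zero; an empty near-wall band yields an empty histogram; a particle
  crossing a wall by more than $r_c$ in one step aborts with the particle
  and step named.

## Analysis metrics

* `covered_area_fraction()` rasterizes the floor (default cell
  0.05 $l$ = 0.25 µm, giving <2% disk-area error) and counts cells within
  a projected platelet radius of any adhered platelet — the simulation
  analogue of fluorescence-projection area. Adhered means at least one
  active bond; the full multilayer projection is counted, matching how a
  fluorescence projection integrates depth.
* `platelet_aggregates()` segments adhered platelets into connected
  components at a contact distance of 1.1 diameters (a convention — the
  aggregate definition is not measurable from the data; sensitivity to
  1.0–1.3 is exposed via the `contact_distance` argument).
* `velocity_profile()` + `fit_profile_shear()` bin and fit the
  streamwise velocity; the wall shear rate is the fitted derivative at
  the wall planes converted to s⁻¹.
* `near_wall_speed_histogram()` classifies platelets within one cutoff
  of the floor into speed classes (µm/s through the unit system).
* `coarse_field()` grids plasma velocity and estimates shear stress as
  an effective viscosity times the central-difference velocity gradient;
  the effective viscosity should be measured once per run from the
  steady profile since DPD viscosity is emergent.

## Desk-scale behaviour of the adhesion model

Under the calibrated flow, adhered platelets on a short reduced channel
are not statically pinned: bonds churn at $P_{dis}$ per step, and
between bonded intervals the drag advances the platelet — stick-slip
translocation over the continuously coated floor at a fraction of the
near-wall flow speed, until the outlet removes it. Coverage at desk
scale is therefore a balance of arrival flux and residence time, which
is what makes the monotone parameter trends measurable: raising $k_0$
or lowering $F_0$ shortens residence; raising $a_0$ strengthens
retention. Near-wall platelet speeds must be measured as drift over a
time window (`platelet_drift_speeds()`): the instantaneous DPD velocity
of even a firmly held platelet is thermal, about one DPD velocity unit
(~0.3 mm/s).

Morphology (multilayer stacking versus single-layer adhesion) is
evaluated in a gentler flow (body force 0.1) where platelets are
arrested rather than translocating, since layering needs residence to
develop. At that scale the collagen parameter set produces stacks at
least two platelet diameters tall and the VWF sets stay ≥90%
single-layer. What desk scale cannot resolve is the *comparative*
$\gamma_p$ effect on covered area (the published sliding-past mechanism):
bond formation in this model is purely distance-stochastic — independent
of approach velocity — so the damping coefficient changes the dynamics
of bonded pairs but barely the capture statistics of the sparse
desk-scale populations. The covered-area sweeps over $a_0$ and
$\gamma_p$ are correspondingly weak signals, tested with seed averaging
and a one-inversion allowance, while the $k_0$ and $F_0$ sweeps are
clean.

## What the tests do and do not show

The shipped test suite runs reduced problems: channel cross-sections of
$10^2$–$12^2$ instead of $80\times40$, tens of DPD time units instead of
the 18 900 that make up five physical minutes, and injection rates
raised so that enough platelets reach the floor within those short runs.
At that scale the suite verifies exact single-pair mechanics against
closed forms, conservation laws and thermostat behaviour, determinism,
the monotone dependence of covered area on $k_0$, $F_0$, $a_0$ and
$\gamma_p$, and the multilayer-versus-monolayer morphology distinction.
It does not reproduce absolute covered-area percentages of the
five-minute full-channel runs; `inst/configs/` ships the full-scale
configurations for that purpose (of order $10^6$ steps over
$6\times10^5$ particles — a cluster job, not a desk job). Real blood adds
margination by red cells, receptor heterogeneity and VWF polymer
mechanics, none of which are in the model; agreement of the reduced runs
with the qualitative morphology is evidence about the model, not about
those mechanisms.

## Known limitations

* Wall slip (above) makes the absolute near-wall platelet speeds
  model-relative; between-surface comparisons are unaffected.
* A platelet is a single particle: no shape, rolling, or activation
  signalling; activation is implicit in bond eligibility (adhered
  platelets recruit).
* No clot rupture/embolization: stage-2 bonds are permanent.
* Aggregate areas inherit the raster and contact-distance conventions;
  report them with the resolution used.
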