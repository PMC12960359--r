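# thrombodpd

Mesoscale simulation of platelet adhesion and aggregation on collagen-
and VWF-coated microchannel surfaces, for researchers in computational
hemodynamics and thrombosis modelling.

Blood perfused over a protein-coated surface deposits platelets in
patterns that depend on the coating: collagen engagement (GPVI/α2β1,
later stabilized by GPIIb/IIIa–fibrinogen) builds scattered multilayer
aggregates, while GPIbα–VWF bonds break quickly and leave scattered
single-platelet adhesion. `thrombodpd` reproduces this with a 3D
dissipative particle dynamics (DPD) model: plasma, wall, coated-surface
and platelet particles interact through the standard DPD forces

    F_C = a_ij (1 - r/r_c) e,
    F_D = -γ (1 - r/r_c)^2 (e·v) e,
    F_R = φ (1 - r/r_c) θ/√Δt e,     φ = √(2 γ k_B T),

and platelet adhesion bonds are viscoelastic spring–dashpot elements

    F_E = a_p (1 - r/r_c) e,  a_p = -a0 (r_a < r ≤ r_c) | a1 (r ≤ r_a),
    F_V = -γ_p (1 - r/r_c)^2 (e·v) e,

whose formation and rupture follow Bell-type stochastic kinetics: at
each timestep a bond under load F ruptures with probability
`P_dis = 1 - exp(-k0 e^{F/F0} Δt)`, and a candidate pair forms a bond
when its uniform draw P_r ≥ P_dis. Bonds older than 300 DPD time units
become permanent (fibrin-stabilized stage 2). Physical units come from
l = 5 µm, E = k_B T (300 K), m = 4.17e-14 kg, giving t = 15.86 ms,
F = 8.28e-16 N, V = 0.32 mm/s.

The engine is compiled (Rcpp) with counter-based noise, so every run is
bit-reproducible from one integer seed. See the vignette
(`vignettes/platelet-adhesion-dpd.Rmd`) for the model assumptions,
parameter meanings and numerical choices.

## Worked example

A reduced collagen-coated channel (10 × 8 × 10 DPD lengths instead of
the full 80 × 20 × 40), driven at the calibrated body force, with
platelets injected at the inlet:

```r
library(thrombodpd)

cfg <- run_config(
  channel = channel_spec(Lx = 10, Ly = 8, Lz = 10, coating = "collagen",
                         injection_rate = 80),
  preset = "collagen", n_steps = 4000, seed = 2, metrics_every = 500)
sim <- run_simulation(cfg)
print(sim)
#> dpd_simulation: preset 'collagen', 4000 steps (dt = 0.01), seed 2
#>   final time   : 0.63 s
#>   covered area : 1.13 %
#>   adhered      : 4 platelets
```

`covered area` is the projected area of adhered platelets as a
percentage of the coated floor — the quantity fluorescence microscopy
measures — and `adhered` counts platelets connected to the coated
surface through the bond graph. At this
reduced scale platelets translocate across the short channel and
evaporate at the outlet, so the instantaneous count stays small and
fluctuates; the full-scale configurations under `inst/configs/` (the
80 × 20 × 40 channel for 5 physical minutes, a cluster-sized job)
accumulate the 10–25% coverage regime.

Flow calibration — a platelet-free channel at full height under the
default body force of 0.45:

```r
cal <- calibrate_flow(seed = 1)
round(c(U_max_mm_s = cal$u_max_mm_s, shear_per_s = cal$wall_shear_per_s), 1)
#> U_max_mm_s shear_per_s
#>       45.3       463.6
```

The fitted wall shear rate sits in the ~500 1/s regime the body force
was calibrated for. The peak velocity includes a large wall-slip offset
— an artifact of soft frozen-particle walls with specular reflection,
discussed with momentum-balance analysis in the vignette.

A command-line front end is installed with the package:

```sh
Rscript inst/scripts/thrombodpd presets
Rscript inst/scripts/thrombodpd run --config inst/configs/collagen_full.yaml --out results/
Rscript inst/scripts/thrombodpd calibrate-flow --quick
```

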