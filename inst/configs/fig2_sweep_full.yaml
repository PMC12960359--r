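# Full-scale base configuration for the stochastic-parameter sweeps over
# the generic coated surface (vary k0 / F0 via overrides on the command
# line or in R). Cluster-scale.
preset: generic_fig2
channel:
  Lx: 80.0
  Ly: 20.0
  Lz: 40.0
  coating: generic
body_force: 0.45
duration_s: 300.0
dt: 0.01
seed: 1
metrics_every: 10000
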