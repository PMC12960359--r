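# Full-scale collagen-coated channel: 80 x 20 x 40 domain, 5 minutes of
# physical time. Cluster-scale: ~1.9e6 timesteps over ~630k particles.
preset: collagen
channel:
  Lx: 80.0
  Ly: 20.0
  Lz: 40.0
  coating: collagen
body_force: 0.45
duration_s: 300.0
dt: 0.01
seed: 1
metrics_every: 10000
snapshot_every: 100000
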