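# Reduced crypt for fast runs: half-scale geometry, coarser BM mesh,
# migration forces scaled with the crypt length, thresholds placed to keep
# a viable stem/Paneth niche.
schema: 1
shape: {z0: 75, r0: 30, lambda1: 0.25, lambda2: 0.1}
params:
  lambda_max: 2.5
  z_p: -50
  z_d: -35
  F_A_paneth: 3.75
  F_A_other: 2.25
experiment:
  kind: steady_state
  warmup: 48
  duration: 48
  obs_dt: 12
  seed: 1
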