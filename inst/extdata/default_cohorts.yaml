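# Default synthetic-cohort configuration: healthy controls and
# methamphetamine users at published VPP group summaries (means and SDs on
# the natural parameter scale), at the study group sizes.
input:
  synthetic:
    model: vpp
    groups:
      HC:
        n: 39
        means: {A: 0.04, alpha: 0.95, cons: 1.62, lambda: 0.26,
                epP: 0.25, epN: -0.5, K: 0.4, w: 0.74}
        sds: {A: 0.01, alpha: 0.05, cons: 0.1, lambda: 0.16,
              epP: 1.18, epN: 1.23, K: 0.17, w: 0.03}
      MUD:
        n: 50
        means: {A: 0.17, alpha: 1.1, cons: 1.01, lambda: 0.1,
                epP: 0.86, epN: -0.21, K: 0.36, w: 0.64}
        sds: {A: 0.07, alpha: 0.07, cons: 0.2, lambda: 0.18,
              epP: 1.81, epN: 1.31, K: 0.17, w: 0.12}
models: [pvl_delta, pvl_decay, vpp]
method: map
qc_min_fraction: 0.05
seed: 1
schedule_seed: 0
outcome_scale: 100
fit:
  n_restarts: 8
  laplace_draws: 200
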