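# Relative-uncertainty sweep over the degree of non-differential
# misclassification (0 = none, 0.5 = half of all units mislabeled).
scenarios:
  - name: sweep_base
    designs:
      srs: 2500
      dss: [500, 500, 500, 500, 500]
    methods: [design_agnostic, model_based, design_based]
    reps: 1000
    seed: 20210713
sweep:
  base: sweep_base
  degrees: [0.0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5]
  pattern: uniform
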