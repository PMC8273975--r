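# Full-scale study configuration: both empirical misclassification
# mechanisms, every design and method, 10,000 replicates per scenario.
scenarios:
  - name: nondifferential
    population:
      size: 100000
      race_probs: [0.82, 0.10, 0.01, 0.05, 0.02]
      trust_coefs: [-0.75, -0.25, -0.50, 1.25, -1.50, 1.00]
      income_coefs: [-2.00, 1.25, 0.25, 1.75, 0.50]
    misclassification: ehr_nondifferential
    matrix_interpretation: bayes_inverted
    designs:
      full_cohort: true
      srs: 2500
      dss: [500, 500, 500, 500, 500]
    methods: [design_agnostic, model_based, design_based]
    reps: 10000
    seed: 20210711
  - name: differential
    population:
      size: 100000
      race_probs: [0.82, 0.10, 0.01, 0.05, 0.02]
      trust_coefs: [-0.75, -0.25, -0.50, 1.25, -1.50, 1.00]
      income_coefs: [-2.00, 1.25, 0.25, 1.75, 0.50]
    misclassification: ehr_differential
    matrix_interpretation: bayes_inverted
    designs:
      full_cohort: true
      srs: 2500
      dss: [500, 500, 500, 500, 500]
    methods: [design_agnostic, model_based, design_based]
    reps: 10000
    seed: 20210712
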