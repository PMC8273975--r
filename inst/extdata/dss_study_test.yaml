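# Reduced-replication profile of dss_study.yaml (2,000 replicates),
# suitable for checking the pipeline end to end in minutes.
scenarios:
  - name: nondifferential
    misclassification: ehr_nondifferential
    designs:
      full_cohort: true
      srs: 2500
      dss: [500, 500, 500, 500, 500]
    reps: 2000
    seed: 20210711
  - name: differential
    misclassification: ehr_differential
    designs:
      full_cohort: true
      srs: 2500
      dss: [500, 500, 500, 500, 500]
    reps: 2000
    seed: 20210712
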