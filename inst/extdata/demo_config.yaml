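# Demonstration pipeline configuration: simulated cohort, default QC and
# threshold ladder. Mirrors demo_pipeline_config(seed = 1).
sim:
  n_subjects: 2000
  n_snps: 5000
  seed: 1
seed: 1
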