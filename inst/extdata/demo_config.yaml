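# Demo pipeline configuration: a small simulated cohort exercised end to end.
seed: 42
simulation:
  n_samples: 150
  n_genes: 600
  n_subgroups: 3
  n_cell_types: 6
  genes_per_set: 30
  noise_sd: 0.3
  depth_sd: 0.25
  outlier_fraction: 0.02
preprocess:
  outlier_z_threshold: 3
  log_transform: true
  pseudocount: 1
clustering:
  n_components: 2
  k_range: [1, 10]
  min_cluster_size: 5
  seed: 42
misassignment:
  R: 18
  p_threshold: 0.05
  fdr_threshold: 0.25
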