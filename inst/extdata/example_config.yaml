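# Example run configuration. Omitted keys fall back to package defaults
# (12 vs 12 discovery cohort of 1108 proteins with 53 up / 9 down planted;
# 10 vs 20 two-timepoint longitudinal cohort on the 21-target panel).
seed: 1

discovery:
  n_case: 12
  n_control: 12
  n_proteins: 1108
  n_de_up: 53
  n_de_down: 9
  de_log2fc_range: [1.5, 3.0]
  proteinuria_log2_mean: 1.0
  proteinuria_log2_sd: 0.3

selection:
  z_abs_threshold: 1.96
  q_threshold: 0.05

fpr_target: 0.10
ci_method: hanley
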