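# Reduced demonstration configuration: a smaller cohort and permutation
# count than the defaults so the full pipeline finishes in well under a
# minute, while still recovering the planted adaptation and release effects.
seed: 1
out_dir: adaptune-demo
behavior:
  n_subjects: 8
simulate:
  n_subjects: 8
  n_runs: 2
release:
  n_perm: 200
  alpha: 0.01
clusters:
  k: 2
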