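# Example run configuration for run_pipeline(); any fs_sim_config() field
# may be overridden here.
n_respondents: 5000   # "n" alone is a YAML boolean; use the long key
seed: 1
n_strata: 15
psus_per_stratum: 2
weight_cv: 0.5
n_cycles: 6
compare_reps: 0
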