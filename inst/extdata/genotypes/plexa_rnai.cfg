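# Packaged cohort configuration: PlexA-RNAi
# Summary-table targets are mean +/- SEM over the cohort; skeletal_mean is the
# expected number of core branches present per arbor (see methods vignette).
name: PlexA-RNAi
n_animals: 37
guidance_error_rate: 0.14
branch_mean: 31
branch_sem: 0.8
total_len_mean: 1219
total_len_sem: 32
varicosity_mean: 68.2
varicosity_sem: 13
skeletal_mean: 13.0
routing_error_rate: 0.08
seed: 104
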