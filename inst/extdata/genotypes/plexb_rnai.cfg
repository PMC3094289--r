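# Packaged cohort configuration: PlexB-RNAi
# Summary-table targets are mean +/- SEM over the cohort; skeletal_mean is the
# expected number of core branches present per arbor (see methods vignette).
name: PlexB-RNAi
n_animals: 42
guidance_error_rate: 0.05
branch_mean: 21.5
branch_sem: 0.7
total_len_mean: 918
total_len_sem: 28
varicosity_mean: 37.4
varicosity_sem: 8
skeletal_mean: 11.7
routing_error_rate: 0.02
seed: 107
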