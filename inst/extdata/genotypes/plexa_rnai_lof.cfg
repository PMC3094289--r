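# Packaged cohort configuration: PlexA-RNAi-LOF
# Summary-table targets are mean +/- SEM over the cohort; skeletal_mean is the
# expected number of core branches present per arbor (see methods vignette).
name: PlexA-RNAi-LOF
n_animals: 10
guidance_error_rate: 0.56
branch_mean: 31
branch_sem: 2.0
total_len_mean: 1305
total_len_sem: 49
varicosity_mean: 79.8
varicosity_sem: 14
skeletal_mean: 12.0
routing_error_rate: 0.20
seed: 105
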