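# Packaged cohort configuration: PlexB-RNAi-LOF
# Summary-table targets are mean +/- SEM over the cohort; skeletal_mean is the
# expected number of core branches present per arbor (see methods vignette).
name: PlexB-RNAi-LOF
n_animals: 20
guidance_error_rate: 0.15
branch_mean: 21.9
branch_sem: 0.9
total_len_mean: 897
total_len_sem: 30
varicosity_mean: 34
varicosity_sem: 10
skeletal_mean: 11.9
routing_error_rate: 0.02
seed: 108
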