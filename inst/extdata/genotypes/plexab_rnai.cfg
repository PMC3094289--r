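# Packaged cohort configuration: PlexAB-RNAi
# Summary-table targets are mean +/- SEM over the cohort; skeletal_mean is the
# expected number of core branches present per arbor (see methods vignette).
name: PlexAB-RNAi
n_animals: 16
guidance_error_rate: 0.00
branch_mean: 30.9
branch_sem: 2
total_len_mean: 1161
total_len_sem: 54
varicosity_mean: 40.9
varicosity_sem: 10
skeletal_mean: 13.0
routing_error_rate: 0.08
seed: 109
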