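# Packaged cohort configuration: PlexA-LOF
# Summary-table targets are mean +/- SEM over the cohort; skeletal_mean is the
# expected number of core branches present per arbor (see methods vignette).
name: PlexA-LOF
n_animals: 15
guidance_error_rate: 0.06
branch_mean: 26.5
branch_sem: 0.7
total_len_mean: 990
total_len_sem: 131
varicosity_mean: 35.5
varicosity_sem: 5
skeletal_mean: 14.6
routing_error_rate: 0.04
seed: 103
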