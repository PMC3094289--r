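# Packaged cohort configuration: PlexB-LOF
# Summary-table targets are mean +/- SEM over the cohort; skeletal_mean is the
# expected number of core branches present per arbor (see methods vignette).
name: PlexB-LOF
n_animals: 21
guidance_error_rate: 0.19
branch_mean: 22.7
branch_sem: 0.6
total_len_mean: 902
total_len_sem: 23
varicosity_mean: 36.1
varicosity_sem: 13
skeletal_mean: 15.2
routing_error_rate: 0.01
seed: 106
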