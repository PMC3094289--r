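# Packaged cohort configuration: 455-Gal4
# Summary-table targets are mean +/- SEM over the cohort; skeletal_mean is the
# expected number of core branches present per arbor (see methods vignette).
name: 455-Gal4
n_animals: 20
guidance_error_rate: 0.15
branch_mean: 24.4
branch_sem: 0.7
total_len_mean: 1045
total_len_sem: 31
varicosity_mean: 35.7
varicosity_sem: 7
skeletal_mean: 15.0
routing_error_rate: 0.02
seed: 102
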