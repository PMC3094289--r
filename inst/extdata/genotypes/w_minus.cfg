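# Packaged cohort configuration: w-
# Summary-table targets are mean +/- SEM over the cohort; skeletal_mean is the
# expected number of core branches present per arbor (see methods vignette).
name: w-
n_animals: 21
guidance_error_rate: 0.00
branch_mean: 22.5
branch_sem: 0.3
total_len_mean: 906
total_len_sem: 19
varicosity_mean: 28.3
varicosity_sem: 4
skeletal_mean: 15.3
routing_error_rate: 0.005
seed: 101
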