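quantity	value
pollen_distance_mean_m	73.80
pollen_distance_sd_m	42.9
seed_distance_mean_m	19.11
seed_distance_sd_m	23.72
sigma_rt_m	41.8
p_p_min	2.603e-227
n_candidates	34
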