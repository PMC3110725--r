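# run configuration for run_full_analysis(); all sizes reduced for a demo
seed: 7
min_population_size: 7
n_perm: 99
n_sim_loci: 5000
n_calibration_loci: 3000
window_rule: hbins
n_random_comparisons: 9
consensus_threshold: 0.7
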