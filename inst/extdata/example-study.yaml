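# Example config for `miscount sim-study`. Unset keys fall back to the
# benchmark defaults (25 clusters x 200 subjects, S1=0.55, C1=0.95,
# S2=0.7, C2=0.8, prior variances 10/100, uniform(0, 3) SD priors).
n_clusters: 10
n_per_cluster: 100
modes: [naive, two_test]
n_replicates: 5
n_iter: 2000
n_burn: 1000
master_seed: 1
out_dir: study_out
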