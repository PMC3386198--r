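# Demo pipeline: simulate a five-copy segmental-duplication set that
# endogenized 25 My ago and duplicated 19.3 My ago, then reconstruct the
# consensus, annotate defects, recover the duplicate set, date it, and run
# a codivergence regression on a simulated congruent host/virus tree pair.
seed: 42
out_dir: pipeline_demo_out
stages:
  simulate:
    genome_length: 3000
    flank_length: 200
    endogenization_time: 25
    duplication_times: [19.3, 19.3, 19.3, 19.3]
    rate_mean: 2.2e-9
    rate_sd: 1.0e-10
  consensus:
    min_support: 0.5
  defects: {}
  dupsets:
    flank_window: 100
    min_flank_identity: 0.90
  date_set:
    rate_mean: 2.2e-9
    rate_sd: 1.0e-10
    n_bootstrap: 200
  codivergence:
    host_tree: builtin
    virus_tree: simulate
    viral_rate: 1.0e-9
    rate_noise_sd: 0.0
    n_permutations: 500
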