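# Default synthetic-scenario configuration for the regenscreen pipeline.
# Values omitted here fall back to the package defaults (default_config()).
seed: 7
outdir: regenscreen_out
stages: [simulate, screen, tree, tfbs, expr]
scenario:
  n_wbr: 3
  n_hra: 5
  n_lra: 8
  n_confirm: 2
  n_background: 200
  n_cbr: 10
  n_paralog: 10
  divergence: 0.1
  indel_rate: 0.005
screen:
  evalue_max_loss: 1.0e-4
  score_min_hra: 100
  grouping: clique
tree:
  n_bootstrap: 100
  n_families: 2
tfbs:
  motif: TAATTAGCTAAT
  plant_rate_target: 0.8
  plant_rate_background: 0.1
  windows: [100, 500, 1000, 3000, 5000, 7500]
  n_background_genes: 200
expr:
  noise_sd: 0.25
  timepoints: [0, 3, 6, 12, 24, 48, 96, 120, 168]
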