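# Example simulated screen: two culture models, one reporter, two
# compounds on 8-point geometric concentration series, 3 biological
# replicates, 16 solvent-control wells per condition.
design:
  models: [2D-DMEM, 3D-DMEM]
  reporters: [BTG2]
  durations: [72h]
  n_replicates: 3
  solvent_control_wells: 16
  compounds:
    cisplatin: {lowest: 0.10, highest: 21.54}
    gemcitabine: {lowest: 0.0037, highest: 0.80}
default_response:
  baseline: 100
  max_fold_change: 1        # null: no reporter induction
  hill_slope: 2
  noise_sd: 10
  ec50: 1.0
response_models:
  - model: 2D-DMEM
    reporter: BTG2
    compound: cisplatin
    baseline: 100
    max_fold_change: 4
    hill_slope: 2
    noise_sd: 10
    onset_concentration: 0.5
  - model: 2D-DMEM
    reporter: BTG2
    compound: gemcitabine
    baseline: 100
    max_fold_change: 3
    hill_slope: 2
    noise_sd: 10
    onset_concentration: 0.02
  - model: 3D-DMEM
    reporter: BTG2
    compound: cisplatin
    baseline: 100
    max_fold_change: 3
    hill_slope: 2
    noise_sd: 10
    onset_concentration: 3.0
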