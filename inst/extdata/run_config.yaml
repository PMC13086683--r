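# Example end-to-end configuration. Any field omitted here keeps the
# package default (see default_run_config()).
seed: 1
model:
  price: 5
  prod_coeff: 0.7
  initial_health: 21
  decline_rate: 0.5
  unit_cost: 0.5
  horizon: 3
  card_cap: 40
cohort:
  n: 210
game:
  mode: calibrated
  sd_group_target: 2.0
  sd_idio_target: 1.5
  sd_group_extraction: 2.0
  sd_idio_extraction: 1.9
analysis:
  specs: [eq_target_round, eq_target_session, eq_extraction_round, eq_extraction_session]
  interactions: false
  method: fgls
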