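# Same ovarian tumour type example, but supplying the temporally validated
# pairwise C-statistics; each is converted to an anticipated Cox-Snell
# R-squared by seeded simulation at resolution time.
outcome:
  counts: [2557, 186, 176, 467, 120]
predictors:
  Q: 17
criteria:
  S_target: 0.9
evidence:
  pairwise_cstat:
    "2,1": 0.85
    "3,1": 0.92
    "4,1": 0.99
    "5,1": 0.95
    "3,2": 0.75
    "4,2": 0.95
    "5,2": 0.87
    "4,3": 0.87
    "5,3": 0.71
    "5,4": 0.82
  sim_size: 1000000
  n_replicates: 10
seed: 2023
epv: [10, 20]
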