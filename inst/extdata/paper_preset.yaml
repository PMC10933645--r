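# Default ground-truth model for the synthetic twice-daily EMA study:
# a four-node self-regulation network (self-control composite, Go/No-go
# response inhibition, momentary anger, anger rumination) measured every
# morning and afternoon over nine weekdays in 62 adolescents.
nodes: [self_control, response_inhibition, anger, anger_rumination]
mu: [74.61, 56.14, 10.97, 12.59]
total_sd: [21.35, 23.80, 21.95, 23.01]
# share of total variance that is between-person (used to split total_sd
# into between-person and within-occasion SDs)
icc: 0.5
# temporal lag-1 matrix, rows = afternoon outcome, cols = morning predictor
temporal:
  - [0.170, 0.174, 0.000, 0.000]
  - [0.000, 0.184, 0.000, 0.000]
  - [0.000, 0.000, -0.006, 0.189]
  - [0.000, 0.000, 0.000, 0.268]
# person-to-person SD of each lag-1 coefficient (random slopes)
slope_sd:
  - [0.065, 0.141, 0.000, 0.000]
  - [0.000, 0.240, 0.000, 0.000]
  - [0.000, 0.000, 0.089, 0.302]
  - [0.000, 0.000, 0.000, 0.415]
# nonzero partial correlations of the afternoon innovations
contemporaneous_partial:
  - pair: [anger, self_control]
    value: -0.138
# nonzero partial correlations of the person means
between_partial:
  - pair: [anger, self_control]
    value: -0.491
  - pair: [anger, response_inhibition]
    value: -0.150
  - pair: [anger, anger_rumination]
    value: 0.291
compliance:
  self_report: 0.85
  task: 0.793
n_persons: 62
n_days: 9
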