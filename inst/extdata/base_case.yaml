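bg_mortality:
  ages:
  - 45.0
  - 50.0
  - 55.0
  - 60.0
  - 65.0
  - 70.0
  - 75.0
  - 80.0
  - 85.0
  - 90.0
  - 95.0
  - 100.0
  values:
  - 0.002491
  - 0.003411582267062
  - 0.004838806730013
  - 0.00710756778978
  - 0.010811950580597
  - 0.017032853075103
  - 0.027788880767037
  - 0.046952099554988
  - 0.082156
  - 0.127181071933143
  - 0.196881847437354
  - 0.304781688510396
  kind: step
mort_lobectomy:
  ages:
  - 45.0
  - 50.0
  - 55.0
  - 60.0
  - 65.0
  - 70.0
  - 75.0
  - 80.0
  - 85.0
  values:
  - 0.0133
  - 0.016643951217136
  - 0.020828655046497
  - 0.026065497632516
  - 0.0326190128606
  - 0.04082024502278
  - 0.051083471190278
  - 0.063927128006992
  - 0.08
  kind: step
mort_sabr:
  point: 0.0037
  low: 0.0
  high: 0.0208
mort_conv_rt:
  point: 0.001
  low: 0.001
  high: 0.001
mort_progression:
  point: 0.6268
  low: 0.4624
  high: 0.8105
p_prog_lob:
  point: 0.04
  low: 0.0133
  high: 0.0742
p_prog_sabr:
  point: 0.079
  low: 0.049
  high: 0.1284
frac_lr_lob:
  point: 0.0
  low: 0.0
  high: 0.0
frac_lr_sabr:
  point: 0.1844
  low: 0.1451
  high: 0.4285
frac_rr_lob:
  point: 0.2784
  low: 0.0952
  high: 0.4
frac_rr_sabr:
  point: 0.1781
  low: 0.0
  high: 0.3333
p_salv_lr_sabr:
  point: 0.2622
  low: 0.2171
  high: 0.4865
p_salv_rr_lob:
  point: 0.3446
  low: 0.3172
  high: 0.3888
p_salv_rr_sabr:
  point: 0.301
  low: 0.2941
  high: 0.3095
p_salv_dm:
  point: 0.0
  low: 0.0
  high: 0.0
p_prog_post_salv_lr_sabr:
  point: 0.0679
  low: 0.0
  high: 0.0799
p_prog_post_salv_rr_lob:
  point: 0.2639
  low: 0.2342
  high: 0.2865
p_prog_post_salv_rr_sabr:
  point: 0.3115
  low: 0.254
  high: 0.3835
p_pn_positive:
  point: 0.0
  low: 0.0
  high: 0.0
n_cycles: 15
cycle_length: 1.0
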