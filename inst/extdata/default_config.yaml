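# Default analysis configuration (values equal the built-in defaults of
# fh_default_config(); any subset may be overridden in a user config).
dlcn:
  aggregate: max
  bands:
    possible: [3, 5]
    probable: [6, 8]
    definite_min: 9
filter:
  rare_af_threshold: 0.005
  conservation_percentile_threshold: 0.7
  predictor_damaging_fraction: 0.5
  excluded_assertions: [benign, likely_benign]
acmg:
  ba1_af: 0.05
  pm2_af: 0.0001
mlpa:
  del_threshold: 0.7
  dup_threshold: 1.3
  homo_del_threshold: 0.25
friedewald:
  direct_threshold: 4.5
  tg_max: 4.5
seed: 1
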