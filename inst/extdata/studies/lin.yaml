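# 2 g twice-daily bolus to steady state; AUC over the final interval.
study: lin
regimen: {amount: 2000, kind: bolus, interval: 12, n_doses: 5}
fe_cutoff: 24
arms:
  - {code: I1, age_range: [21, 74], proportion_female: 0.333,
     renal: {clcr_range: [51, 94], normalized: false}}
  - {code: I2, age_range: [58, 75], proportion_female: 0.375,
     renal: {clcr_range: [10, 35], normalized: false}, horizon: 72}
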