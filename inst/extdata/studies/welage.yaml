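study: welage
regimen: {amount: 1000, kind: bolus}
proportion_female: 0.143
fe_cutoff: 24
arms:
  - {code: F1, age_range: [30, 36], renal: {clcr_range: [110, 122], normalized: false}}
  - {code: F2, age_range: [49, 69], renal: {clcr_range: [30, 60], normalized: false}}
  - {code: F3, age_range: [27, 91], renal: {clcr_range: [21, 29.5], normalized: false}}
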