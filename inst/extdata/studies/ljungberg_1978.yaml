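study: ljungberg_1978
regimen: {amount: 2000, kind: bolus}
proportion_female: 0
fe_cutoff: 12
arms:
  - {code: B1, age_range: [23, 31], renal: normal}
  - {code: B2, age_range: [63, 76], renal: normal}
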