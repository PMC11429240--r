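study: naber
regimen: {amount: 2000, kind: bolus}
fe_cutoff: 12
arms:
  - {code: C1, age_range: [24, 32], proportion_female: 0.5, renal: normal}
  - {code: C2, age_range: [63, 83], proportion_female: 0.154, renal: normal}
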