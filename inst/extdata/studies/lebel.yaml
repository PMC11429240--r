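# 1 g IV bolus (dose per the comparison table); fe reported at 24 h.
study: lebel
regimen: {amount: 1000, kind: bolus}
fe_cutoff: 24
arms:
  - {code: D1, age_range: [19, 29], proportion_female: 0.5, renal: normal}
  - {code: D2, age_range: [57, 73], proportion_female: 0, renal: normal}
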