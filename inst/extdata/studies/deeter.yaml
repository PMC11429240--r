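study: deeter
regimen: {amount: 2000, kind: infusion, infusion_duration: 0.5}
fe_cutoff: 12
arms:
  - {code: E, age_range: [67, 74], proportion_female: 0.5, renal: normal, horizon: 36}
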