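# Model-application design: 1 g bolus to 65-80 y cohorts per renal stage.
study: model_ri_elderly
regimen: {amount: 1000, kind: bolus}
proportion_female: 0.5
fe_cutoff: 24
arms:
  - {code: M1, age_range: [65, 80], renal: normal}
  - {code: M2, age_range: [65, 80], renal: mild}
  - {code: M3, age_range: [65, 80], renal: moderate}
  - {code: M4, age_range: [65, 80], renal: severe}
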