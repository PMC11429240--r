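# Model-application design: 2 g bolus to four age bands, 50% female,
# renal function normal for age.
study: model_age_bands
regimen: {amount: 2000, kind: bolus}
proportion_female: 0.5
fe_cutoff: 12
arms:
  - {code: H1, age_range: [25, 35], renal: normal}
  - {code: H2, age_range: [45, 55], renal: normal}
  - {code: H3, age_range: [65, 75], renal: normal}
  - {code: H4, age_range: [85, 95], renal: normal, horizon: 36}
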