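# 2 g IV bolus across four age decades, renal function normal for age.
study: ljungberg_1984
regimen: {amount: 2000, kind: bolus}
fe_cutoff: 12
arms:
  - {code: A1, age_range: [18, 39], proportion_female: 0.286, renal: normal}
  - {code: A2, age_range: [40, 59], proportion_female: 0.5, renal: normal}
  - {code: A3, age_range: [60, 79], proportion_female: 0.231, renal: normal}
  - {code: A4, age_range: [80, 88], proportion_female: 0.444, renal: normal}
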