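study: ackerman
regimen: {amount: 1000, kind: bolus}
proportion_female: 0.364
fe_cutoff: 24
arms:
  - {code: C1, age_range: [26, 27], renal: {clcr_range: [90, 113], normalized: true}}
  - {code: C3, age_range: [33, 74], renal: {clcr_range: [34, 45], normalized: true}}
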