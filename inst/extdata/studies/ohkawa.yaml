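# 0.5 g IV bolus; adults spanning normal renal function to severe
# impairment; CLcr reported normalized to 1.73 m2.
study: ohkawa
regimen: {amount: 500, kind: bolus}
proportion_female: 0.256
fe_cutoff: 24
arms:
  - {code: A1, age_range: [20, 65], renal: {clcr_range: [105.2, 133], normalized: true}}
  - {code: A2, age_range: [20, 87], renal: {clcr_range: [63.1, 89.1], normalized: true}}
  - {code: A3, age_range: [20, 87], renal: {clcr_range: [30, 56.8], normalized: true}}
  - {code: A4, age_range: [20, 87], renal: {clcr_range: [8.3, 29.2], normalized: true}}
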