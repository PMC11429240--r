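# 0.5 g IV bolus; male adults grouped by reported CLcr band.
study: saito
regimen: {amount: 500, kind: bolus}
proportion_female: 0
fe_cutoff: 24
arms:
  - {code: B1, age_range: [20, 50], renal: {clcr_range: [90, 130], normalized: true}}
  - {code: B2, age_range: [20, 50], renal: {clcr_range: [60, 90], normalized: true}}
  - {code: B3, age_range: [20, 50], renal: {clcr_range: [30, 60], normalized: true}}
  - {code: B4, age_range: [20, 50], renal: {clcr_range: [10, 30], normalized: true}}
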