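study: van_dalen
regimen: {amount: 1000, kind: bolus}
proportion_female: 0.39
fe_cutoff: 24
arms:
  - {code: G1, age_range: [34, 88], renal: {clcr_range: [93, 134], normalized: false}}
  - {code: G2, age_range: [34, 88], renal: {clcr_range: [72, 86], normalized: false}}
  - {code: G3, age_range: [34, 88], renal: {clcr_range: [30, 59], normalized: false}}
  - {code: G4, age_range: [34, 88], renal: {clcr_range: [9, 20], normalized: false}}
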