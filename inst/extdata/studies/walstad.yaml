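# 1 g IV bolus except 0.5 g in the severe-impairment arm.
study: walstad
regimen: {amount: 1000, kind: bolus}
proportion_female: 0.568
fe_cutoff: 24
arms:
  - {code: H1, age_range: [28, 89], renal: {clcr_range: [50, 90], normalized: false}}
  - {code: H2, age_range: [28, 89], renal: {clcr_range: [31, 50], normalized: false}}
  - {code: H3, age_range: [28, 89], renal: {clcr_range: [16, 30], normalized: false},
     regimen: {amount: 500, kind: bolus}}
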