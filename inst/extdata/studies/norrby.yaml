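study: norrby
regimen: {amount: 1000, kind: infusion, infusion_duration: 0.333}
proportion_female: 0.43
fe_cutoff: 24
arms:
  - {code: E1, age_range: [57, 77], renal: {clcr_range: [92, 146], normalized: false}}
  - {code: E2, age_range: [69, 84], renal: {clcr_range: [60, 76], normalized: false}}
  - {code: E3, age_range: [62, 78], renal: {clcr_range: [47, 54], normalized: false}}
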