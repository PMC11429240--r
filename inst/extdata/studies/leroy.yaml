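# Weight-based dosing: 15 mg/kg IV bolus; CLcr from timed endogenous
# creatinine collections (mL/min, not BSA-normalized).
study: leroy
regimen: {mg_per_kg: 15, kind: bolus}
proportion_female: 0.5
fe_cutoff: 24
arms:
  - {code: D1, age_range: [22, 31], renal: {clcr_range: [110, 141], normalized: false}}
  - {code: D2, age_range: [26, 74], renal: {clcr_range: [39, 73], normalized: false}}
  - {code: D3, age_range: [26, 74], renal: {clcr_range: [13.8, 27], normalized: false}}
  - {code: D4, age_range: [26, 74], renal: anuric}
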