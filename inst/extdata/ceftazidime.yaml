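# Ceftazidime PBPK input record.
# Physicochemistry and binding, the systemic renal clearance of a healthy
# reference adult, and the per-hepatocyte intrinsic biliary clearance.
molecular_weight: 546.580      # g/mol
log_p: -3.750                  # octanol:buffer, neutral species
compound_type: diprotic_acid
pka1: 2.430
pka2: 2.890
blood_to_plasma: 0.550
fu_plasma: 0.9
binding_protein: albumin       # human serum albumin
cl_renal_ref: 6.0              # L/h, healthy reference adult
clint_biliary: 0.085           # uL/min per 1e6 hepatocytes
clint_biliary_cv: 30           # percent, inter-individual CV
kp_scalar: 1.0
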