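# One-compartment IV-infusion parameters for gemcitabine (GEMZAR dosing)
dose_mg: 1250
infusion_h: 1
clearance_L_h: 168
vc_L_kg: 1.45
body_weight_kg: 70
f: 0.99949
sim_duration_h: 24
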