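compound,dose_mg,infusion_h,clearance_L_h,vc_L_kg,body_weight_kg,f_percent,fup_percent,bp_ratio
Gem,1250,1,168,1.45,70,99.949,84.61,1.12
Pen,1250,1,168,0.14,70,99.999,22.50,0.93
Cys-Pen,1250,1,168,0.11,70,99.999,26.72,0.92
Gem-Cys-Pen,1250,1,168,0.17,70,100.000,12.91,0.98
pVEC,1250,1,168,0.16,70,100.000,13.35,1.13
Cys-pVEC,1250,1,168,0.11,70,100.000,15.53,1.12
Gem-Cys-pVEC,1250,1,168,0.18,70,99.998,42.89,1.20
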