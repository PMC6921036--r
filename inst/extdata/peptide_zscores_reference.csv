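peptide,z1,z2,z3
Pen,2.3233,0.4802,0.6731
Cys-Pen,2.0865,0.5016,0.6364
pVEC,1.0880,0.2586,1.0435
Cys-pVEC,0.9411,0.2895,0.9911
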