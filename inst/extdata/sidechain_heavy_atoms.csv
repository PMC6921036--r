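residue,heavy_atoms
A,1
R,7
N,4
D,4
C,2
Q,5
E,5
G,0
H,6
I,4
L,4
K,5
M,4
F,7
P,3
S,2
T,3
W,10
Y,8
V,3
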