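residue,donors,acceptors
A,0,0
R,5,1
N,2,2
D,0,4
C,1,0
Q,2,2
E,0,4
G,0,0
H,1,1
I,0,0
L,0,0
K,3,1
M,0,0
F,0,0
P,0,0
S,1,2
T,1,2
W,1,0
Y,1,2
V,0,0
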