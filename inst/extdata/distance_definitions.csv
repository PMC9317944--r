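name,kind,points
A,dist,10 19
Bl,dist,10 13
Br,dist,16 19
C,dist,13 16
D,dist,11 15
E,dist,18 20
F,dist,22 28
G,dist,22 34
H,dist,2 12
I,dist,7 17
J,dist,10 28
K,dist,19 34
Nl,dist,10 12
Nr,dist,19 17
Ol,dist,10 14
Or,dist,19 21
Pl,dist,28 37
Pu,dist,28 31
Ql,dist,34 37
Qu,dist,34 31
R,dist,22 10
S,dist,22 19
T,dist,0 28
U,dist,9 34
Vl,dist,28 13
Vr,dist,34 16
W,dist,28 34
X,dist,25 31
L,brow_height,0 1 2 3 4
M,brow_height,5 6 7 8 9
Wl,perimeter,28 29 30 31 37 38 39
Wr,perimeter,31 32 33 34 35 36 37
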