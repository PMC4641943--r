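residue	energy
A	5.33
R	4.18
N	3.71
D	3.59
C	7.93
Q	3.87
E	3.65
G	4.48
H	5.10
I	8.83
L	8.47
K	2.95
M	8.95
F	9.03
P	3.87
S	4.09
T	3.93
W	7.66
Y	5.89
V	7.63
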