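aa	disordered	ordered	tm
A	0.030	0.080	0.110
R	0.070	0.040	0.000
N	0.045	0.040	0.000
D	0.090	0.040	0.000
C	0.002	0.020	0.010
Q	0.075	0.030	0.000
E	0.145	0.040	0.000
G	0.080	0.070	0.040
H	0.020	0.020	0.000
I	0.005	0.080	0.200
L	0.010	0.120	0.300
K	0.070	0.040	0.000
M	0.002	0.030	0.020
F	0.005	0.060	0.120
P	0.120	0.030	0.000
S	0.150	0.060	0.000
T	0.060	0.050	0.000
W	0.001	0.015	0.010
Y	0.005	0.045	0.010
V	0.015	0.090	0.180
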