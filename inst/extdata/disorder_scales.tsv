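aa	kyte_doolittle	top_idp
A	1.8	0.06
R	-4.5	0.180
N	-3.5	0.007
D	-3.5	0.192
C	2.5	0.02
Q	-3.5	0.318
E	-3.5	0.736
G	-0.4	0.166
H	-3.2	0.303
I	4.5	-0.486
L	3.8	-0.326
K	-3.9	0.586
M	1.9	-0.397
F	2.8	-0.697
P	-1.6	0.987
S	-0.8	0.341
T	-0.7	0.059
W	-0.9	-0.884
Y	-1.3	-0.510
V	4.2	-0.121
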