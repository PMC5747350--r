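S	1	TF
TF	1	P1
TF	1	P2
M1	-1	M1
P1	1	and1
M1	1	and1
and1	1	M2
P2	1	and2
M2	1	and2
D	-1	and2
and2	1	M3
M3	-1	M3
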