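CholER	-1	and1
SREBP1	-1	and1
HC25	-1	and1
and1	1	SREBP
SREBP	1	SREBP1
SREBP	1	SREBP2
T09In	1	LXR
GWIn	1	LXR
ACAT2	1	ACAT2act
HMGCS1	1	HMGCS1act
SREBP2	1	HMGCR
SREBP2	1	HMGCS1
SREBP2	1	ACAT2
SREBP2	1	LDLR
SREBP2	1	NPC1
SREBP2	1	INSIG1
SREBP2	1	SQLE
SREBP2	1	LSS
SREBP2	1	IDI1
SREBP2	1	MVD
SREBP2	1	DHCR7
SREBP2	1	DHCR24
SREBP2	1	FDFT1
SREBP2	1	MSMO1
LXR	1	ABCA1
LXR	1	SREBP1
SREBP1	1	FASN
SREBP1	1	ELOVL6
LPDS	-1	CholMedia
siSREBF1	-1	SREBP1
siSREBF2	-1	SREBP2
siLDLR	-1	LDLR
siNPC1	-1	NPC1
siHMGCS1	-1	HMGCS1
AtorvaEx	1	AtorvaIn
T09Ex	1	T09In
GWEx	1	GWIn
AtorvaIn	1	OHAtorva
AtorvaIn	1	AtorvaLactone
GWIn	1	OHGW
ACAT2act	1	and2
AcetylCoA	1	and2
and2	1	AcetoacetylCoA
HMGCS1act	1	and3
AcetylCoA	1	and3
AcetoacetylCoA	1	and3
and3	1	HMGCoA
HMGCR	1	and4
HMGCoA	1	and4
AtorvaIn	-1	and4
and4	1	Mevalonate
Mevalonate	1	CholER
CholMedia	1	and5
LDLR	1	and5
NPC1	1	and5
and5	1	CholER
AcetylCoA	-1	AcetylCoA
CholER	-1	CholER
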