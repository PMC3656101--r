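#protein	ARC40
	ARC19	ARC15	ACT1	LAS17	MYO5	MYO3	PAN1	CRN1
ARC19	-	0	0	0	0	0	0	0
ARC15	0	-	0	0	0	0	0	0
ACT1	0	0	-	1	1	1	1	1
LAS17	0	0	1	-	1	1	1	1
MYO5	0	0	1	1	-	1	1	1
MYO3	0	0	1	1	1	-	1	1
PAN1	0	0	1	1	1	1	-	1
CRN1	0	0	1	1	1	1	1	-
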