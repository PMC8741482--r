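name	start	end	family
C2A	1	130	C2
FerA	140	280	FerA
C2B	300	420	C2
DysF-N	450	600	DysF
C2C	650	780	C2
DysF-C	800	960	DysF
C2D	1000	1130	C2
C2E	1200	1330	C2
C2F	1450	1580	C2
C2G	1700	1830	C2
TM	2047	2069	TM
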