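gene	in_obesity	in_igf1	count	label
ATF2	Y	N	0	SN
DUSP8	N	Y	0	SN
GADD45G	Y	N	0	SN
HRAS	N	Y	0	SN
IKBKB	Y	N	0	SN
MAP4K3	Y	N	0	SN
MAPK9	N	Y	0	SN
MAPKAPK5	N	Y	0	SN
MAX	Y	N	0	SN
PPM1B	Y	N	0	SN
PPP3R1	N	Y	0	SN
RAPGEF2	Y	N	0	SN
RPS6KA4	N	Y	0	SN
SOS1	Y	N	0	SN
CHUK	N	Y	1	SN
FGF13	N	Y	1	SN
FGFR2	N	Y	1	SN
MAP2K6	N	Y	1	SN
PAK2	Y	N	1	SN
RASA1	Y	N	1	SN
RPS6KA3	N	Y	1	SN
DDIT3	N	Y	2	SN
FLNA	N	Y	2	SN
IL1R1	N	Y	2	SN
MAP2K4	Y	N	2	SN
FGFR4	Y	N	3	SN
DUSP5	N	Y	4	SC
MAP3K8	N	Y	4	SC
DUSP6	Y	Y	8	SC
FOS	N	Y	8	SC
DUSP4	Y	Y	12	SC
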