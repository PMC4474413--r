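occurrence	expected_pct	n_genes	genes
0	80.89	19	POLA2;NCAPG2;PLAUR;FZD1;CCT2;DNMT1;PIK3R1;POLR2J;TGFBR2;VCL;NCAPD2;POLR2D;HGF;FGFR1;MIS12;ARPC1B;CD93;CDK4;NCAPH
1	17.14	5	MMP13;CBX3;CHEK1;LAMA4;TCP1
2	1.89	7	CDC6;CAV2;GNG12;CD44;MCM2;CALD1;CFD
3	0.08	2	CCL2;PDGFRA
4	0.00	1	TUBB
5	0.00	1	EDNRA
6	0.00	1	COL3A1
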