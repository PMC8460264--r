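model	stem	pos5	pos3
old	P7_proximal	73	96
old	P7_proximal	74	95
old	P7_proximal	75	94
old	P7_proximal	76	93
old	P7_proximal	77	92
old	P7_proximal	78	91
old	P7_distal	80	89
old	P7_distal	81	88
old	P7_distal	82	87
pseudoknot	P7_proximal	73	96
pseudoknot	P7_proximal	74	95
pseudoknot	P7_proximal	75	94
pseudoknot	P7_proximal	76	93
pseudoknot	P7_proximal	77	92
pseudoknot	P7_proximal	78	91
pseudoknot	P8	11	89
pseudoknot	P8	12	88
pseudoknot	P8	13	87
pseudoknot	P8	14	86
pseudoknot	P8	15	85
pseudoknot	P8	16	84
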