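group	term_id	term_kind	k	n	K	N	fdr_printed	annotation
M1_Top500	PF00112	PFAM	19	500	110	25890	1.58324e-11	Papain family cysteine protease
M1_Top500	GO:0008234	GO	19	500	121	25890	2.43945e-11	cysteine-type peptidase activity
M2_Top500	PF00067	PFAM	16	500	146	25890	9.31946e-07	Cytochrome P450
M3_Top500	GO:0055114	GO	51	500	1078	25890	1.54695e-07	oxidation-reduction process
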