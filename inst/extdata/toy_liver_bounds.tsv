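condition	reaction_id	lower	upper	source
early_5-7h	EX_glc	90	110	exchange
early_5-7h	EX_glycogen	-60	0	exchange
early_5-7h	EX_glyc	-45	0	exchange
early_5-7h	EX_lac	-120	10	exchange
early_5-7h	EX_ala	-44	-5	exchange
early_5-7h	EX_ffa	-1	0	exchange
early_5-7h	EX_ket	0	40	exchange
early_5-7h	PYGL	43.2	52.8	mfa
early_5-7h	GNG_glyc	13.5	16.5	mfa
early_5-7h	GNG_pyr	33.3	40.7	mfa
early_5-7h	S1_SHORT	0	0	mfa
early_5-7h	S2_SHORT	0	1000	mfa
early_5-7h	S3_SHORT	0	1000	mfa
late_10-13h	EX_glc	63	77	exchange
late_10-13h	EX_glycogen	-60	0	exchange
late_10-13h	EX_glyc	-45	0	exchange
late_10-13h	EX_lac	-120	10	exchange
late_10-13h	EX_ala	-44	-35	exchange
late_10-13h	EX_ffa	-6	-5	exchange
late_10-13h	EX_ket	18	45	exchange
late_10-13h	PYGL	1.449	1.771	mfa
late_10-13h	GNG_glyc	14.742	18.018	mfa
late_10-13h	GNG_pyr	46.809	57.211	mfa
late_10-13h	S1_SHORT	0	1000	mfa
late_10-13h	S2_SHORT	0	0	mfa
late_10-13h	S3_SHORT	0	0	mfa
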