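family	pattern	note
RBFOX	GCAUG|UGCAU	(U)GCAUG core recognized by RBFOX1/2/3
hnRNP F/H	GGGG	G-run
MBNL	[CU]GC[CU]	YGCY
CELF	UGUU|GUGU	UG/GU-rich
PTB	UCUC|CUCU	CU-rich pyrimidine tract
hnRNP L	CACA|ACAC	CA repeat
ESRP	UGG|GGU	UGG/GU-rich
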