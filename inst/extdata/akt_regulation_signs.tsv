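gene_id	pathway	sign	reference	subsystem
GAPDH	AKT	1	Tanner	carbohydrate
GLUT1	AKT	1	Barthel	carbohydrate
GYS1	AKT	1	Deprez_Elstrom	carbohydrate
HK1	AKT	1	Gottlob_Majewski	carbohydrate
HK2	AKT	1	Gottlob_Majewski	carbohydrate
G6PC	AKT	-1	Elstrom	carbohydrate
PCK1	AKT	-1	Elstrom	carbohydrate
ACLY	AKT	1	Deprez	fatty_acid
ME1	AKT	1	Deprez	fatty_acid
PFKFB2	AKT	1	Elstrom_Rathmell	fatty_acid
HMGCR	AKT	1	Deprez	fatty_acid
HMGCS1	AKT	1	Deprez	fatty_acid
ACC	AKT	1	Porstmann	fatty_acid
SREBF1	AKT	1	Porstmann	fatty_acid
SREBF2	AKT	1	Deprez_Porstmann	fatty_acid
FASN	AKT	1	Porstmann	fatty_acid
ATIC	AKT	1	Wang	purine_pyrimidine
HPRT1	AKT	1	Wang	purine_pyrimidine
TALDO1	AKT	1	Wang	purine_pyrimidine
TKT	AKT	1	Saha	purine_pyrimidine
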