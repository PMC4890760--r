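gene_id	observed
GAPDH	down_in_M
GLUT1	down_in_E
GYS1	down_in_M
HK1	down_in_M
HK2	down_in_M
G6PC	NA
PCK1	NA
ACLY	down_in_M
ME1	down_in_M
PFKFB2	NA
HMGCR	down_in_M
HMGCS1	down_in_M
ACC	NA
SREBF1	down_in_E
SREBF2	NA
FASN	down_in_M
ATIC	down_in_M
HPRT1	down_in_M
TALDO1	down_in_M
TKT	down_in_M
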