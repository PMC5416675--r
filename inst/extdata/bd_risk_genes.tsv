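gene	analysis	locus
ALDH6A1	E	14q24.3
ARID4B	E	1q42.3
ATP6V1F	E	7q32.1
ATP8B2	E	1q21.3
CLASRP	E	19q13.32
CLPTM1	E	19q13.32
COG5	E	7q22.3
CPQ	M	8q22.1
DNAJC7	E	17q21.2
FASTK	E	7q36.1
FBXW11	E	5q35.1
GLUL	M	1q25.3
GTF2A1	E	14q31.1
HINT3	E	6q22.32
HOOK2	M	19p13.13
HSPA1L	E	6p21.33
HUWE1	E	Xp11.22
IL7R	E	5p13.2
LCE2D	M	1q21.3
LSM14B	E	20q13.33
MAGI2	M	7q21.11
MED1	E	17q12
MTF2	E	1p22.1
NLK	M	17q11.2
NUCKS1	E	1q32.1
PBX2	E	6p21.32
PCNX	M	14q24.2
PEX2	E	8q21.13
PITPNM1	E	11q13.2
PQLC2L	M	3q25.32
PRR14	E	16p11.2
SAFB2	E	19p13.3
SLC45A4	M	8q24.3
SNORA65	E	9q33.3
SUZ12	E	17q11.2
TAF15	E	17q12
THOC2	E	Xq25
UBE2E1	E	3p24.2
ZNF195	M	11p15.4
ZNF234	E	19q13.31
ZNF641	E	12q13.11
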