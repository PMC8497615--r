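gene	pathways
APEX1	BER
APEX2	BER
LIG3	BER
MUTYH	BER
NEIL1	BER
NEIL2	BER
NTHL1	BER
OGG1	BER
PARP1	BER
POLB	BER
SMUG1	BER
UNG	BER
XRCC1	BER
ALKBH2	DR
ALKBH3	DR
MGMT	DR
ATR	DS;Other
ATRIP	DS
CHEK1	DS;Other
CHEK2	DS;Other
CLSPN	DS
HUS1	DS
RAD1	DS
RAD17	DS
RAD9A	DS
TOPBP1	DS;Other
BRCA1	FA;HDR
BRCA2	FA;HDR
BRIP1	FA;HDR
FANCA	FA
FANCB	FA
FANCC	FA
FANCD2	FA
FANCE	FA
FANCF	FA
FANCG	FA
FANCI	FA
FANCL	FA
FANCM	FA
PALB2	FA;HDR
UBE2T	FA
BARD1	FA;HDR
BLM	HDR
EME1	HDR
GEN1	HDR
H2AFX	HDR
MRE11A	HDR
MUS81	HDR
NBN	HDR
POLQ	HDR
RAD50	HDR
RAD51	HDR
RAD51B	HDR
RAD51C	HDR;FA
RAD51D	HDR
RAD52	HDR
RAD54B	HDR
RAD54L	HDR
RBBP8	HDR
TP53BP1	HDR
XRCC2	HDR
XRCC3	HDR
EXO1	MMR
MLH1	MMR
MLH3	MMR
MSH2	MMR
MSH3	MMR
MSH6	MMR
PMS1	MMR
PMS2	MMR
CUL3	NER
CUL5	NER
CUL4A	NER
DDB1	NER
DDB2	NER
ERCC1	NER
ERCC2	NER
ERCC3	NER
ERCC4	NER
ERCC5	NER
ERCC6	NER
ERCC8	NER
POLE	NER
XPA	NER
XPC	NER
DCLRE1C	NHEJ
LIG4	NHEJ
NHEJ1	NHEJ
PRKDC	NHEJ
XRCC4	NHEJ
XRCC5	NHEJ
XRCC6	NHEJ
DUT	NP
NUDT1	NP
RRM2B	NP
MAD2L2	TLS
POLH	TLS
POLI	TLS
POLK	TLS
POLN	TLS
REV1	TLS
REV3L	TLS
ATM	Other
ATRX	Other
HERC2	Other
MDC1	Other
PTEN	Other
SMARCA4	Other
TP53	Other
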