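AF4
AR
ARNT
BRD4
CDX2
CEBPA
CEBPD
CTBP1
CTBP2
CTCF
CTNNB1
DROSHA
FLI1
FOXA1
FOXA2
FOXM1
GATA1
GATA2
GF1
GF1B
JARID2
KDM2B
KLF1
KLF4
KLF5
LEF1
LMO2
LUZP1
MBD3
MEIS1
MITF
MTF2
NFKB1
NR3C1
NR3C2
OCT4
OLIG2
P300
POU3F2
POU5F1
PPAR
REST
RING1B
RUNX2
SMAD3
SMAD4
SMARCA4
SMARCD1
SOX11
SOX2
STAT1
STAT3
SUZ12
TAL1
TBX3
TCF3
TCF4
TEAD4
TOP2B
TP53
TP63
UBTF
WT1
YAP1
ZFP57
ZNF217
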