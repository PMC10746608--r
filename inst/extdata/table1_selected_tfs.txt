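ARID3B
CBX2
CUX2
DMRT3
EEA1
ELF2
ETV4
FOXD3
FOXI1
FOXJ3
GRHL3
HMGA2
IKZF1
JRKL
KLF4
LIN28B
LTF
MAFK
MBD2
MITF
NPAS3
NR2F2
NR3C1
NR3C2
NRF1
OLIG1
PAX2
PAX3
PHF20
PLAG1
PPARD
PRMT3
SETBP1
SKI
SOX10
SOX2
SOX6
SOX9
SREBF1
TFCP2L1
THYN1
TLX3
ZFAT
ZNF236
ZNF286A
ZNF286B
ZNF436
ZNF492
ZNF516
ZNF521
ZNF555
ZNF679
ZNF780B
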