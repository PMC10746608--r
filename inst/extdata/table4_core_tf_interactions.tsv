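symbol_a	symbol_b	source
SOX2	ARID3B	biogrid_table4
SOX2	CBX2	biogrid_table4
SOX2	ELF2	biogrid_table4
SOX2	MBD2	biogrid_table4
SOX2	MITF	biogrid_table4
SOX2	SOX2	biogrid_table4
SOX2	SOX6	biogrid_table4
SOX2	ARNT	biogrid_table4
SOX2	CEBPD	biogrid_table4
SOX2	CTBP1	biogrid_table4
SOX2	CTBP2	biogrid_table4
SOX2	CTCF	biogrid_table4
SOX2	CTNNB1	biogrid_table4
SOX2	FLI1	biogrid_table4
SOX2	KDM2B	biogrid_table4
SOX2	LUZP1	biogrid_table4
SOX2	MBD3	biogrid_table4
SOX2	POU5F1	biogrid_table4
SOX2	RUNX2	biogrid_table4
SOX2	SMARCA4	biogrid_table4
SOX2	SMARCD1	biogrid_table4
SOX2	TBX3	biogrid_table4
SOX2	TCF3	biogrid_table4
SOX2	TP63	biogrid_table4
SOX2	UBTF	biogrid_table4
SOX2	YAP1	biogrid_table4
NR3C1	NR3C2	biogrid_table4
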