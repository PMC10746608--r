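SOX2 E1 synthetic	synthetic stand-in ChIP experiment	KLF4	MITF	NR3C1	NR3C2	GDUM001	GDUM002	GDUM003
SOX2 E2 synthetic	synthetic stand-in ChIP experiment	MITF	NR3C1	GDUM004	GDUM005
KLF4 E1 synthetic	synthetic stand-in ChIP experiment	SOX2	GDUM001	GDUM006
MITF E1 synthetic	synthetic stand-in ChIP experiment	SOX2	GDUM007	GDUM008
NR3C1 E1 synthetic	synthetic stand-in ChIP experiment	GDUM002	GDUM009	GDUM010
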