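alias	canonical
HNF3beta	FOXA2
HNF3b	FOXA2
Foxa	FOXA1
ERalpha-a	ESR1
PU1	SPI1
Sfpi1	SPI1
POL2	POLR2A
POL2B	POLR2A
KAP1	TRIM28
CJUN	JUN
CMYC	MYC
NRSF	REST
BAF155	SMARCC1
INI1	SMARCB1
Srf	SRF
AP-4	TFAP4
MEF-2	MEF2A
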