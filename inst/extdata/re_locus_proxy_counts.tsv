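locus	n_proxies
MYO1D	34
TJP2	18
RDH5	2
CD55	88
CNDP2	29
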