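label	description	count
1a	eQTL + TF binding + matched TF motif + matched DNase footprint + DNase peak	1
1b	eQTL + TF binding + any motif + DNase footprint + DNase peak	5
1c	eQTL + TF binding + matched TF motif + DNase peak	0
1d	eQTL + TF binding + any motif + DNase peak	5
1e	eQTL + TF binding + matched TF motif	0
1f	eQTL + TF binding/DNase peak	25
2a	TF binding + matched TF motif + matched DNase footprint + DNase peak	1
2b	TF binding + any motif + DNase footprint + DNase peak	24
2c	TF binding + matched TF motif + DNase peak	0
3a	TF binding + any motif + DNase peak	48
3b	TF binding + matched TF motif	1
4	TF binding + DNase peak	85
5	TF binding or DNase peak	241
6	Motif hit	226
ND	No data	206
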