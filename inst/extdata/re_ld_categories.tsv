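locus	index_rsid	proxy_rsid	r2_bin	label	is_index
MYO1D	rs17183295	rs10512441	0.9	1a	0
MYO1D	rs17183295	rs17183628	0.9	1d	0
MYO1D	rs17183295	rs17781142	0.9	1f	0
TJP2	rs11145746	rs1538583	1.0	1b	0
TJP2	rs11145746	rs11145326	0.8	1f	0
TJP2	rs11145746	rs11145488	1.0	1f	0
RDH5	rs3138142	rs3138142	1.0	1d	1
RDH5	rs3138144	rs3138144	1.0	1f	1
CD55	rs1652333	rs1652333	1.0	1f	1
CD55	rs1652333	rs2802236	1.0	1b	0
CD55	rs1652333	rs2564974	1.0	1b	0
CD55	rs1652333	rs2564978	1.0	1b	0
CD55	rs1652333	rs12095015	1.0	1d	0
CD55	rs1652333	rs6700168	1.0	1d	0
CD55	rs1652333	rs1346720	0.8	1f	0
CD55	rs1652333	rs7545125	1.0	1f	0
CD55	rs1652333	rs1572275	1.0	1f	0
CD55	rs1652333	rs4844592	1.0	1f	0
CD55	rs1652333	rs10864231	1.0	1f	0
CD55	rs1652333	rs1507758	1.0	1f	0
CD55	rs1652333	rs1507760	1.0	1f	0
CNDP2	rs12971120	rs12971120	1.0	1f	1
CNDP2	rs12971120	rs8084410	0.9	1b	0
CNDP2	rs12971120	rs11151960	0.8	1d	0
CNDP2	rs12971120	rs747176	0.8	1f	0
CNDP2	rs12971120	rs3764509	0.9	1f	0
CNDP2	rs12971120	rs12605820	0.8	1f	0
CNDP2	rs12971120	rs2303463	0.8	1f	0
CNDP2	rs12971120	rs4891557	0.8	1f	0
CNDP2	rs12971120	rs4891559	0.9	1f	0
CNDP2	rs12971120	rs3829640	1.0	1f	0
CNDP2	rs12971120	rs2278161	1.0	1f	0
CNDP2	rs12971120	rs2278159	0.8	1f	0
CNDP2	rs12971120	rs2278158	0.8	1f	0
CNDP2	rs12971120	rs734559	1.0	1f	0
CNDP2	rs12971120	rs3794950	0.8	1f	0
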