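chrom	pos	rsid	allele	locus	region_class	region_detail	histone_marked	dnase	eqtl	motifs_altered	protein_bound	is_index
1	207387765	rs1346720	T/C	CD55	intergenic	69 kb 3' of C4BPA	-	-	+	-	SETDB1*	0
1	207424726	rs7545125	A/G	CD55	intergenic	70 kb 5' of CD55	+	-	+	-; DIx2, Foxo, Ik-2, NF-AT, NF-AT1, YY1	CEBPB*	0
1	207456473	rs12095015	T/C	CD55	intergenic	38 kb 5' of CD55	+	+	+	MGA; Foxp1, Irf, SRF, Zec	CDX2, JUN; CJUN	0
1	207470459	rs1652333	G/A	CD55	intergenic	24 kb 5' of CD55	+	-	+	-; Ap-4, E2A, Evi-1, Mef2, Myf, RP58	MEF-2, TCF21, AP-4, TFAP4, MYF6	1
1	207472188	rs2802236	T/C	CD55	intergenic	23 kb 5' of CD55	+	+	+	HOXA5(Hox-1.3); Eomes, Hoxa5, Pax5, Pax6, Zfp187	FOXA1, ESR1, EP300, GATA3*; ERALPHA-A	0
1	207478979	rs1572275	C/A	CD55	intergenic	16 kb 5' of CD55	+	+	+	-; AIRE, Pou5f1	SMARCC1, RAD21*, POLR2A, CEBPB*, TAF1*, NFYB, TBP*, CHD2, TFAP2A	0
1	207483444	rs2564974	G/A	CD55	intergenic	11 kb 5' of CD55	+	+	+	Irx-3, Irx3, Irx4, Irx6, TFAP4; CDP, Irx, Myb	STAT1, SMARCC1, TCF7L2, SP1, EP300, TCF12, MYC, ELF1*, RCOR1, MEF2A, TEAD4, SPI1, BHLHE40, JUND*, GATA2*, TAL1*, JUN, USF1, MAX*, GATA1, POLR2A, CBX3, SIRT6*; PU1, POL2, BAF155, CJUN, CMYC, INI1	0
1	207494415	rs2564978	T/C	CD55	intergenic	399 bp 5' of CD55	+	+	+	FXR/RXR-alpha*	E2F1, MTA3, POLR2A*, SPI1, ELF1*, TAF1, CEBPB*, TBL1XR1, EP300*, TBP*, FOS, TRIM28, MYC*, STAT3*, KDM5B, ZNF143, HDAC1, MAX*, SP4, CDX2, MXI1, GATA1, STAT1, CTCF*, JUNB, PHF8, RAD21*, BACH1, TCF12, GABPB1, ZKSCAN1, IRF1, SIN3A, SETDB1, NFKB1*, HNF4A; PU1, GTF2F1, POL2S2, SMC3, CEBPB	0
1	207501210	rs4844592	T/A	CD55	intronic		+	+	+	Srf, SPI1, SPIC; HDAC2	POLR2A*	0
1	207502533	rs6700168	A/C	CD55	intronic		+	+	+	IRC900814	POLR2A*, NFYA, CHD2, MAX, RCOR1, SMC3, ZKSCAN1, ZNF143; POL24H8, GTF2F1, POL2B, POL2S2	0
1	207506328	rs10864231	T/G	CD55	intronic		-	+	+	-; PL2F, Pax5	POLR2A*, TAF1; POL24H8	0
1	207507480	rs1507758	G/C	CD55	intronic		+	+	+	-; Foxp1	POLR2A*, SETDB1*	0
1	207509364	rs1507760	C/T	CD55	intronic		+	+	+	-; NK-kappaB	POLR2A*, EBF1, CHD1, EP300, CTCF*, GATA1, RAD21*, NFKB1*, TBP, SP1, YY1, TBL1XR1, CHD2, RUNX3, BHLHE40, MXI1; POL24H8, POL2B	0
9	71733141	rs11145326	C/G	TJP2	intergenic	3.1 kb 5' of TJP2	-	-	+	-; MSX2, Pax6, STAT, Sox	PAX6, SOX15, SOX7, SOX8	0
9	71770938	rs11145488	G/A	TJP2	intronic		+	+	+	-; Nanog, Sox		0
9	71791546	rs1538583	A/G	TJP2	intronic		+	+	+	POU3F2; Foxa, Pbx3, Pou1f1, Pou3f2, STAT	EBF1*, PML, NFIC	0
12	56114768	rs3138144	G/C	RDH5	intronic		+	+	+	-; BCL, NRSF	MYC, CEBPB, POLR2A, EP300, RUNX3, ZBTB7A, RXRA, MAZ, SMC3, CTCF*, E2F1	1
12	56115584	rs3138142	C/T	RDH5	exon_synonymous		+	+	+	Nr2f2; PLAG1*, RXRA*	POLR2A	1
17	31184630	rs17183628	T/C	MYO1D	intronic		+	-	+	Zfp691, ZFP652; FXR, Pax4, VDR	TEAD4	0
17	31187215	rs17781142	G/C	MYO1D	intronic		+	+	+	-; LBP-1	JUN, PML, GATA2*, POLR2A, MAX, RCOR1, CEBPB, STAT2, GATA1*, STAT5A, EBF1*, TAF7, JUND, EP300, CCNT2*, MAZ, IRF1, NFKB1, EBF1, TBL1XR1, MYC*	0
17	31239644	rs10512441	C/T	MYO1D	intergenic	15 kb 5' of TMEM98	-	+	+	HNF3beta; Foxa, Foxj2	EP300*, POLR2A*, CTCF*, TRIM28, FOXA2*, JUND, GATA3*, UBTF, SRF*, TAF1, YY1, ZBTB7A, ZNF143, SP1, ARID3A, HDAC2, FOXA1*, TBP*, MYC, PML, PHF8, MAZ; KAP1, HDAC2	0
18	72154930	rs747176	G/A	CNDP2	intergenic	8.6 kb 5' of CNDP2	+	-	+	-; Mrg, Pax5, Pbx3, TAL1, Tgif1		0
18	72167123	rs3764509	C/G	CNDP2	utr5		+	+	+	-; Pbx3	POU2F2, SIN3A*, STAT3*, STAT1*, TAF1*, USF1*, TBP, USF2, SAP30, RUNX3, BHLHE40, CTCF, E2F6*, YY1*, CEBPB*; MAX, POLR2A, POL24H8, SIN3AK20, MYC, NFKB, MXI1, ETS1	0
18	72167801	rs12605820	G/A	CNDP2	intronic		+	+	+	Sfpi1; Foxo, HP1, Mef2, TCF12		0
18	72168485	rs8084410	T/C	CNDP2	intronic		+	+	+	TEF*, TEAD1, TEAD4, TEAD3; DMRT4, RFX5, TCF12	SIN3A	0
18	72168607	rs2303463	G/A	CNDP2	exon_synonymous		+	+	+	EGR2, EGR3		0
18	72170298	rs4891557	C/T	CNDP2	intronic		+	-	+	ESR1, EWSR1-FLI1; ERalpha-a, EWSR1-FLI1, Irf, RXRA, VDR		0
18	72170396	rs4891559	G/A	CNDP2	intronic		+	-	+	-; Bbx, Foxj2		0
18	72174022	rs12971120	A/G	CNDP2	intronic		+	+	+			1
18	72174979	rs3829640	A/G	CNDP2	intronic		+	+	+	-; Bcl6b		0
18	72176082	rs2278161	T/C	CNDP2	exon_nonsynonymous		+	+	+	-; BDP1	GATA2*, TAL1*, MYC	0
18	72177231	rs11151960	G/A	CNDP2	intronic		+	+	+	Sox13, Zic1, Zic2; E2F, Tel2	PAX5	0
18	72178160	rs2278159	T/C	CNDP2	exon_synonymous		+	+	+	-; Maf		0
18	72178299	rs2278158	G/T	CNDP2	intronic		+	+	+	-; Ets, TATA		0
18	72179578	rs734559	G/A	CNDP2	intronic		+	+	+	Lyf-1, PTF1-beta; CEBPB, HMG-1Y, Ik-1, IK-2, NF-AT, NF-AT1, PTF1-beta, Pou5f1		0
18	72182964	rs3794950	G/A	CNDP2	intronic		+	+	+	-; Jundm2		0
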