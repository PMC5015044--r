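rsid	chrom	pos	pvalue	locus	study
rs524952	15	35005886	1.1e-13	GJD2	23andMe
rs12971120	18	72174022	2.4e-09	CNDP2	23andMe
rs17183295	17	31207103	6.1e-09	MYO1D	23andMe
rs11145746	9	71747708	8.3e-09	TJP2	23andMe
chr14:54413001	14	54413001	3.7e-08	BMP4	23andMe
rs920000001	2	233380143	5.2e-10	PRSS56	23andMe
rs920000002	4	81952356	6.8e-09	BMP3	23andMe
rs920000003	6	129823773	9.9e-09	LAMA2	23andMe
rs920000004	8	60169469	1.3e-08	TOX	23andMe
rs920000005	13	100687543	2.1e-09	ZIC2	23andMe
rs920000006	15	82385304	3.6e-10	RASGRF1	23andMe
rs920000007	8	40734662	4.1e-08	ZMAT4	23andMe
rs920000008	9	77149837	1.7e-08	RORB	23andMe
rs920000009	17	68100000	2.9e-08	KCNJ2	23andMe
rs920000010	11	40149305	3.2e-08	LRRC4C	23andMe
rs920000011	17	11203544	1.9e-08	SHISA6	23andMe
rs920000012	11	85330557	2.6e-08	DLG2	23andMe
rs920000013	2	178935272	3.4e-08	PDE11A	23andMe
rs920000014	2	172967505	4.3e-08	DLX1	23andMe
rs920000015	10	78943304	1.5e-08	KCNMA1	23andMe
rs920000016	14	54416497	2.7e-08	BMP4	23andMe
rs920000017	14	36144933	4.8e-08	PABPCP2	23andMe
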