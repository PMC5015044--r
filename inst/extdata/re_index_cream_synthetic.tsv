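rsid	chrom	pos	pvalue	locus	study
rs524952	15	35005886	3.0e-12	GJD2	CREAM
rs1652333	1	207470459	1.9e-09	CD55	CREAM
rs3138142	12	56115584	2.0e-11	RDH5	CREAM
rs3138144	12	56114768	9.0e-09	RDH5	CREAM
chr8:60178580	8	60178580	4.0e-08	CHD7	CREAM
rs910000001	2	233385396	1.2e-10	PRSS56	CREAM
rs910000002	4	81959966	2.3e-09	BMP3	CREAM
rs910000003	6	129834628	7.5e-09	LAMA2	CREAM
rs910000004	8	60179086	1.1e-08	TOX	CREAM
rs910000005	13	100691367	3.3e-09	ZIC2	CREAM
rs910000006	15	82396791	4.4e-11	RASGRF1	CREAM
rs910000007	2	233406998	2.8e-08	CHRNG	CREAM
rs910000008	3	53847407	3.9e-08	CACNA1D	CREAM
rs910000009	10	94924334	8.7e-09	CYP26A1	CREAM
rs910000010	10	60265404	1.6e-08	BICC1	CREAM
rs910000011	11	105556598	2.2e-08	GRIA4	CREAM
rs910000012	13	100818092	3.1e-08	PCCA	CREAM
rs910000013	6	73643289	1.4e-09	KCNQ5	CREAM
rs910000014	16	7459683	2.5e-08	RBFOX1	CREAM
rs910000015	10	86005560	4.6e-08	RGR	CREAM
rs910000016	3	141093285	1.8e-08	ZBTB38	CREAM
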