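snp	trait	gene	effect_allele	effect_freq	beta	p	freq_ceu	ref_snp	ref_effect_allele	ref_beta	ref_study	note
rs4895441	MCV	HBS1L/MYB	G	0.27	0.854	5.03e-13	0.22	rs4895441	A	-0.008	Ganesh2009	effect reported on major allele
rs4895441	MCV	HBS1L/MYB	G	0.27	0.854	5.03e-13	0.22	rs9402686	A	0.818	Soranzo2009
rs4895441	RBC	HBS1L/MYB	G	0.27	-0.081	2.46e-13	0.22	rs9483788	T	0.014	Ganesh2009
rs855791	MCV	TMPRSS6	A	0.44	-0.620	5.41e-09	0.39	rs855791	A	-0.127	Benyamin2009
rs855791	MCV	TMPRSS6	A	0.44	-0.620	5.41e-09	0.39	rs2413450	A	-0.005	Ganesh2009
rs855791	MCH	TMPRSS6	A	0.44	-0.289	1.10e-12	0.39	rs855791	A	-0.330	Chambers2009
rs855791	MCH	TMPRSS6	A	0.44	-0.289	1.10e-12	0.39	rs5756506	C	0.137	Soranzo2009
rs1800562	MCV	HFE	A	0.06	1.087	5.84e-07	0.04	rs1800562	A	0.222	Benyamin2009
rs1800562	MCV	HFE	A	0.06	1.087	5.84e-07	0.04	rs1800562	A	0.012	Ganesh2009
rs1800562	MCV	HFE	A	0.06	1.087	5.84e-07	0.04	rs1800562	A	1.408	Soranzo2009
rs1800562	MCV	HFE	A	0.06	1.087	5.84e-07	0.04	rs198846	A	0.820	Chambers2009
rs1800562	MCH	HFE	A	0.06	0.494	2.76e-09	0.04	rs198846	A	0.370	Chambers2009
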