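class	n_variants	MY	MFY	MPY	MFP	MPP
specific_genes_5kb	631689	0.022	0.022	0.004	0.042	0.126
deg_5kb	127947	0.122	0.092	0.117	0.090	0.116
de_lncrna_5kb	177123	0.000	0.007	0.014	0.000	0.000
de_mirna_5kb	1796	0.001	0.000	0.001	0.000	0.002
rna_editing_100kb	77442	0.028	0.001	0.008	0.043	0.110
dmr	61661	0.000	0.000	0.000	0.000	0.000
enhancer	183768	0.114	0.089	0.132	0.057	0.172
eqtl	32830	0.012	0.098	0.000	0.094	0.001
sqtl	55166	0.139	0.094	0.078	0.305	0.172
other	2062309	0.299	0.334	0.353	0.208	0.160
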