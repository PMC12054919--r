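model	MY	MFY	MPY	MFP	MPP
GBLUP	75.13	72.18	72.77	84.05	83.07
MultiBLUP	75.43	72.18	72.98	84.04	83.35
BayesR	75.75	73.72	73.07	85.26	83.88
BayesRC	75.96	73.74	73.28	85.26	84.56
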