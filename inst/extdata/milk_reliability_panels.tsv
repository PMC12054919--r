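panel	MY	MFY	MPY	MFP	MPP
671K	75.13	72.18	72.77	84.05	83.07
625K	75.48	72.23	73.13	84.10	83.37
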