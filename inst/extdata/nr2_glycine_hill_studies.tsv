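study	subunit	ec50_uM	hill_slope
Matsui1995	NR2A	0.97	1.5
Matsui1995	NR2B	0.84	2
Matsui1995	NR2C	0.75	2
Matsui1995	NR2D	0.56	1
Kutsuwada1992	NR2A	2.1	1.5
Kutsuwada1992	NR2B	0.3	1.5
Kutsuwada1992	NR2C	0.2	1.5
Kutsuwada1992	NR2D
Woodward1995	NR2A	0.84	1.5
Woodward1995	NR2B	0.19	2
Woodward1995	NR2C	0.15	1.5
Woodward1995	NR2D	0.096	1
Laurie1994	NR2A	3.7	1
Laurie1994	NR2B	2.1	1.5
Laurie1994	NR2C	0.36	1.5
Laurie1994	NR2D	2.3	1.5
Chen2008	NR2A	1.31	1.66
Chen2008	NR2B	0.72	1.84
Chen2008	NR2C	0.34	1.81
Chen2008	NR2D	0.13	1.32
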