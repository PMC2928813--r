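17	14000000	15500000	CMT1A_synthetic
1	158000000	159000000	CMT1B_synthetic
16	14100000	14900000	CMT1C_synthetic
10	64000000	64600000	CMT1D_synthetic
8	8100000	8800000	CMT1F_synthetic
1	11900000	12400000	CMT2A_synthetic
3	149000000	150200000	CMT2B_synthetic
12	53900000	54600000	CMT2C_synthetic
7	115000000	115900000	CMT2D_synthetic
8	24700000	25300000	CMT2E_synthetic
7	45500000	46200000	CMT2F_synthetic
12	110000000	111200000	CMT2G_synthetic
1	226000000	227500000	CMT2K_synthetic
12	120200000	121000000	CMT2L_synthetic
8	75200000	76400000	CMT4A_synthetic
11	89300000	90200000	CMT4B1_synthetic
11	111300000	112300000	CMT4B2_synthetic
5	148000000	149400000	CMT4C_synthetic
8	23000000	23800000	CMT4D_synthetic
19	49900000	50700000	CMT4E_synthetic
19	5200000	5900000	CMT4F_synthetic
10	69700000	70600000	CMT4G_synthetic
X	70400000	71300000	CMTX1_synthetic
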