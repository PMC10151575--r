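chrom	mb	n_snps	wppa	pct_var	pct_region_p2	pct_region_p3	pct_region_p4	pct_region_p5	pct_region_p6
1	14	43	0.99	2.23	1.15	0.65	0.63	3.23	0.31
3	9	33	0.96	1.51	0.86	1.84	1.14	0.20	1.01
7	97	40	0.88	1.10	1.83	0.88	1.09	0.20	0.18
10	8	24	0.99	1.93	0.99	1.16	0.25	0.21	0.61
12	5	22	0.90	1.18	0.96	0.6	0.27	2.41	0.31
14	8	39	0.89	1.14	0.32	0.27	0.81	0.30	0.91
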