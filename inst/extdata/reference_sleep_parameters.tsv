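variable	mean_FRG	sd_FRG	mean_CTR	sd_CTR	t	p_printed
tst_min	430.59	26.03	433.68	30.27	-0.51	0.620
sol_min	17.29	11.20	16.32	12.03	0.37	0.715
waso_min	43.21	22.61	53.03	33.69	-1.53	0.146
se_pct	87.77	4.22	86.53	7.22	0.88	0.390
n1_min	57.32	14.68	37.21	7.31	5.75	<0.001
n2_min	217.35	27.25	216.53	33.32	0.14	0.887
n3_min	92.97	23.58	94.06	22.96	-0.32	0.752
rem_min	62.94	8.13	85.88	19.44	-5.65	<0.001
n1_pct	13.37	3.54	8.66	1.94	5.84	<0.001
n2_pct	50.39	4.84	49.83	6.23	0.50	0.626
n3_pct	21.63	5.42	21.77	5.30	-0.16	0.872
rem_pct	14.61	1.62	19.75	4.01	-6.16	<0.001
rem_latency_min	126.82	40.91	135.76	59.73	-0.56	0.584
n_awakenings	21.71	9.69	19.88	5.79	0.98	0.341
remfr	75.52	10.03	23.12	5.43	23.29	<0.001
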