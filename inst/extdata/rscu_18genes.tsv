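codon	BDNF	COMT	CYP1A2	CYP2B6	CYP2C19	CYP2C9	CYP2D6	CYP3A4	CYP3A5	HLA-A	HLA-B	HTR2A	MC4R	MTHFR	SLC6A4	UGT2B15	UGT1A4	TPH2
TTT	0.57	0.33	0.24	0.62	0.97	1.13	0.30	1.25	1.00	0.00	0.00	0.96	0.67	0.71	0.70	1.58	1.25	1.14
TTC	1.43	1.67	1.76	1.39	1.03	0.88	1.70	0.75	1.00	2.00	2.00	1.04	1.33	1.29	1.30	0.42	0.75	0.86
TTA	0.00	0.00	0.00	0.10	0.64	0.62	0.00	0.81	0.84	0.00	0.00	0.95	0.45	0.09	0.10	0.90	0.38	0.51
TTG	2.00	0.43	0.79	0.48	0.64	0.72	0.36	0.71	0.94	0.00	0.00	0.53	1.20	0.46	0.69	0.80	0.86	0.77
CTT	1.43	0.57	0.39	0.86	1.18	1.14	0.18	1.32	1.13	0.21	0.21	0.84	0.90	0.74	0.49	1.30	0.86	1.02
CTC	0.57	0.57	1.28	2.57	1.29	1.24	1.09	1.42	1.31	1.93	1.71	1.37	1.35	1.20	1.87	0.70	1.14	1.15
CTA	0.29	0.29	0.10	0.19	0.21	0.21	0.46	0.51	0.66	0.21	0.21	0.74	0.15	0.09	0.49	0.60	0.48	0.64
CTG	1.71	4.14	3.44	1.81	2.04	2.07	3.91	1.22	1.13	3.64	3.86	1.58	1.95	3.42	2.36	1.70	2.29	1.92
ATT	1.20	0.40	0.58	0.86	1.50	1.94	0.20	1.30	1.14	0.23	0.30	0.88	1.08	0.18	0.70	1.22	1.50	1.94
ATC	0.60	2.60	2.31	1.82	1.25	0.79	2.20	1.30	1.14	2.31	2.40	1.59	1.62	2.65	1.93	0.94	1.23	0.88
ATA	1.20	0.00	0.12	0.32	0.25	0.27	0.60	0.40	0.72	0.46	0.30	0.53	0.31	0.18	0.38	0.84	0.27	0.18
GTT	0.42	0.17	0.12	0.46	0.52	0.80	0.00	0.72	0.82	0.18	0.32	0.36	0.80	0.22	0.62	1.33	0.98	1.29
GTC	0.84	0.35	1.58	1.23	1.16	0.93	0.80	0.92	0.71	0.73	0.96	1.58	1.44	1.00	0.98	1.09	0.80	0.39
GTA	0.63	0.00	0.24	0.62	0.39	0.13	0.10	0.31	0.47	0.00	0.16	0.36	0.00	0.22	0.00	0.12	0.09	0.39
GTG	2.11	3.48	2.06	1.69	1.94	2.13	3.10	2.05	2.00	3.09	2.56	1.70	1.76	2.56	2.40	1.46	2.13	1.94
TCT	0.67	0.00	0.90	0.96	1.39	1.50	0.26	1.16	1.50	1.83	1.62	1.36	1.20	0.40	1.32	1.61	1.46	1.50
TCC	1.00	1.33	1.95	1.92	0.92	0.94	2.09	0.97	0.94	1.30	1.62	1.47	0.69	2.13	1.61	0.29	1.64	1.33
TCA	1.33	1.33	0.45	0.24	1.15	1.13	0.52	1.36	1.13	0.52	0.46	1.36	1.20	0.40	0.73	1.76	0.73	1.33
TCG	0.67	0.67	0.15	0.24	0.23	0.00	1.30	0.00	0.19	0.26	0.23	0.45	0.17	0.27	0.15	0.29	0.36	0.00
AGT	1.33	0.00	0.60	0.72	0.46	0.38	0.00	1.16	1.13	0.78	0.69	0.45	1.37	1.20	0.59	1.46	0.91	1.00
AGC	1.00	2.67	1.95	1.92	1.85	2.06	1.83	1.36	1.13	1.30	1.39	0.91	1.37	1.60	1.61	0.59	0.91	0.83
CCT	2.00	0.29	1.14	0.77	1.33	1.16	0.53	1.37	1.18	0.71	0.44	0.86	1.50	0.67	0.93	1.39	0.80	1.04
CCC	1.60	1.71	1.71	1.81	1.73	1.68	2.11	1.03	1.18	2.35	1.56	0.86	1.50	2.10	1.20	1.57	1.47	1.39
CCA	0.40	1.14	0.69	1.29	0.67	0.90	0.84	1.60	1.65	0.00	0.44	1.43	1.00	0.86	1.20	1.04	1.07	1.39
CCG	0.00	0.86	0.46	0.13	0.27	0.26	0.53	0.00	0.00	0.94	1.56	0.86	0.00	0.38	0.67	0.00	0.67	0.17
ACT	1.26	0.00	0.69	0.92	1.33	1.33	0.64	0.59	1.00	0.43	0.50	1.19	0.94	0.80	0.61	1.39	0.97	1.04
ACC	1.26	2.22	1.79	2.00	1.33	1.33	2.40	1.33	1.38	2.29	2.50	1.19	1.88	2.27	1.74	0.87	1.52	1.19
ACA	0.84	1.33	1.10	0.77	1.19	1.00	0.48	1.78	1.38	0.71	0.83	1.33	0.71	0.53	0.70	1.57	1.10	1.33
ACG	0.63	0.44	0.41	0.31	0.15	0.33	0.48	0.30	0.25	0.57	0.17	0.30	0.47	0.40	0.96	0.17	0.41	0.44
GCT	0.86	0.76	0.39	0.89	2.59	1.78	0.88	2.00	1.52	0.91	1.05	1.38	1.52	1.13	1.04	0.97	1.24	1.04
GCC	1.14	1.71	2.97	2.07	0.71	1.33	2.15	1.40	1.33	1.37	1.47	1.79	1.14	1.54	1.57	1.52	1.71	1.04
GCA	1.71	0.76	0.52	0.89	0.71	0.89	0.49	0.60	0.95	0.34	0.42	0.83	1.14	0.82	0.78	1.24	0.67	1.63
GCG	0.29	0.76	0.13	0.15	0.00	0.00	0.49	0.00	0.19	1.37	1.05	0.00	0.19	0.51	0.61	0.28	0.38	0.30
TAT	0.00	0.25	0.20	0.38	1.27	1.17	0.67	1.38	1.41	0.43	0.25	0.71	0.93	0.29	0.65	1.24	0.74	1.05
TAC	2.00	1.75	1.80	1.63	0.73	0.83	1.33	0.63	0.59	1.57	1.75	1.29	1.07	1.71	1.36	0.76	1.26	0.95
CAT	0.80	0.25	0.77	0.56	1.00	0.83	0.75	1.00	0.67	1.00	0.89	1.00	0.40	0.29	0.57	1.20	1.00	1.20
CAC	1.20	1.75	1.23	1.44	1.00	1.17	1.25	1.00	1.33	1.00	1.11	1.00	1.60	1.71	1.43	0.80	1.00	0.80
CAA	1.00	0.18	0.08	0.44	0.63	0.71	0.36	0.67	0.75	0.00	0.10	0.67	1.00	0.11	0.56	1.07	0.46	0.63
CAG	1.00	1.82	1.92	1.56	1.38	1.29	1.64	1.33	1.25	2.00	1.90	1.33	1.00	1.89	1.44	0.93	1.54	1.37
AAT	1.11	0.00	0.56	0.53	0.77	0.77	0.50	1.00	1.11	0.40	0.00	0.93	1.20	0.60	0.91	1.48	1.13	1.18
AAC	0.89	2.00	1.44	1.47	1.23	1.23	1.50	1.00	0.89	1.60	2.00	1.07	0.80	1.40	1.09	0.52	0.87	0.82
AAA	1.06	0.14	0.39	1.17	1.20	1.14	0.17	1.11	1.15	0.33	0.20	0.74	0.75	0.29	0.86	1.05	0.83	1.26
AAG	0.94	1.86	1.62	0.83	0.80	0.86	1.83	0.90	0.85	1.67	1.80	1.26	1.25	1.71	1.14	0.96	1.17	0.74
GAT	0.46	0.24	0.35	0.40	1.00	0.86	0.44	1.23	1.11	0.42	0.36	1.10	1.40	0.38	0.89	1.39	0.80	0.80
GAC	1.54	1.77	1.65	1.60	1.00	1.14	1.57	0.77	0.89	1.58	1.64	0.90	0.60	1.63	1.11	0.61	1.20	1.20
GAA	1.00	0.35	0.15	0.73	1.03	1.13	0.20	1.23	1.10	0.00	0.07	1.22	0.57	0.48	0.89	1.19	0.92	1.32
GAG	1.00	1.65	1.85	1.27	0.97	0.88	1.80	0.77	0.90	2.00	1.93	0.78	1.43	1.52	1.11	0.82	1.08	0.68
TGT	0.86	0.75	0.86	1.60	0.92	0.92	0.67	1.43	0.80	0.40	0.33	0.93	0.93	0.55	0.44	1.56	1.46	0.92
TGC	1.14	1.25	1.14	0.40	1.08	1.08	1.33	0.57	1.20	1.60	1.67	1.07	1.07	1.46	1.56	0.44	0.55	1.08
CGT	0.00	0.00	0.00	0.38	1.11	1.14	0.62	0.27	0.52	0.00	0.20	0.00	0.55	0.63	0.32	0.00	0.24	0.64
CGC	0.57	2.40	1.64	1.50	0.67	0.29	4.00	0.27	0.52	1.86	1.80	0.92	1.09	1.58	1.26	0.71	1.20	0.21
CGA	1.14	0.00	0.18	0.94	0.00	0.00	0.31	0.55	0.52	0.41	0.40	0.46	0.00	0.79	0.63	2.12	0.72	0.86
CGG	1.14	1.80	2.36	1.50	1.11	1.14	0.62	0.55	0.52	1.66	1.20	1.85	1.09	1.58	1.90	0.00	1.20	1.29
AGA	1.43	0.00	0.36	0.75	2.44	2.86	0.00	2.73	2.61	1.03	1.40	0.46	1.09	0.79	0.00	2.12	1.20	1.71
AGG	1.71	1.80	1.46	0.94	0.67	0.57	0.46	1.64	1.30	1.03	1.00	2.31	2.18	0.63	1.90	1.06	1.44	1.29
GGT	1.11	0.38	0.41	0.52	0.14	0.29	0.61	0.31	0.44	0.27	0.30	0.67	0.75	0.71	0.64	1.19	0.67	0.86
GGC	1.56	2.29	1.79	1.29	1.29	1.29	1.33	0.92	0.74	1.47	1.63	0.89	1.25	1.96	0.96	0.59	1.20	1.14
GGA	0.44	0.19	0.55	1.16	2.00	1.86	0.49	2.15	2.07	0.67	0.74	1.11	1.25	0.62	0.96	1.78	1.20	1.43
GGG	0.89	1.14	1.24	1.03	0.57	0.57	1.58	0.62	0.74	1.60	1.33	1.33	0.75	0.71	1.44	0.44	0.93	0.57
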