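gene	at_skew	gc_skew	purine_skew	pyrimidine_skew	amino_skew	keto_skew
BDNF	0.139	0.106	0.007	-0.027	0.113	-0.132
COMT	0.038	0.067	-0.248	-0.221	-0.184	-0.284
CYP1A2	0.000	-0.075	-0.144	-0.217	-0.217	-0.144
CYP2B6	0.025	-0.145	0.019	-0.151	-0.127	-0.006
CYP2C19	0.020	-0.034	0.111	0.057	0.077	0.091
CYP2C9	0.020	-0.038	0.126	0.069	0.089	0.106
CYP2D6	-0.082	-0.061	-0.290	-0.271	-0.345	-0.214
CYP3A4	0.035	0.000	0.144	0.109	0.144	0.109
CYP3A5	0.058	-0.024	0.160	0.079	0.136	0.102
HLA-A	0.111	0.051	-0.250	-0.305	-0.201	-0.350
HLA-B	0.115	0.043	-0.251	-0.318	-0.210	-0.356
HTR2A	-0.027	-0.078	0.107	0.056	0.029	0.134
MC4R	-0.159	-0.063	0.032	0.127	-0.032	0.189
MTHFR	0.083	0.002	-0.117	-0.196	-0.115	-0.197
SLC6A4	-0.086	-0.020	-0.091	-0.025	-0.111	-0.005
UGT2B15	-0.012	0.059	0.153	0.221	0.210	0.164
UGT1A4	-0.042	0.005	-0.038	0.009	-0.033	0.004
TPH2	0.080	0.046	0.099	0.065	0.145	0.019
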