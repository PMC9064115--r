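sample_id	study_id	label	disease
EX01_S0001	EX01	0	synthetic
EX01_S0002	EX01	0	synthetic
EX01_S0003	EX01	0	synthetic
EX01_S0004	EX01	0	synthetic
EX01_S0005	EX01	0	synthetic
EX01_S0006	EX01	0	synthetic
EX01_S0007	EX01	0	synthetic
EX01_S0008	EX01	0	synthetic
EX01_S0009	EX01	0	synthetic
EX01_S0010	EX01	0	synthetic
EX01_S0011	EX01	0	synthetic
EX01_S0012	EX01	0	synthetic
EX01_S0013	EX01	0	synthetic
EX01_S0014	EX01	0	synthetic
EX01_S0015	EX01	0	synthetic
EX01_S0016	EX01	0	synthetic
EX01_S0017	EX01	0	synthetic
EX01_S0018	EX01	0	synthetic
EX01_S0019	EX01	0	synthetic
EX01_S0020	EX01	0	synthetic
EX01_S0021	EX01	0	synthetic
EX01_S0022	EX01	0	synthetic
EX01_S0023	EX01	0	synthetic
EX01_S0024	EX01	0	synthetic
EX01_S0025	EX01	0	synthetic
EX01_S0026	EX01	0	synthetic
EX01_S0027	EX01	0	synthetic
EX01_S0028	EX01	0	synthetic
EX01_S0029	EX01	0	synthetic
EX01_S0030	EX01	0	synthetic
EX01_S0031	EX01	1	synthetic
EX01_S0032	EX01	1	synthetic
EX01_S0033	EX01	1	synthetic
EX01_S0034	EX01	1	synthetic
EX01_S0035	EX01	1	synthetic
EX01_S0036	EX01	1	synthetic
EX01_S0037	EX01	1	synthetic
EX01_S0038	EX01	1	synthetic
EX01_S0039	EX01	1	synthetic
EX01_S0040	EX01	1	synthetic
EX01_S0041	EX01	1	synthetic
EX01_S0042	EX01	1	synthetic
EX01_S0043	EX01	1	synthetic
EX01_S0044	EX01	1	synthetic
EX01_S0045	EX01	1	synthetic
EX01_S0046	EX01	1	synthetic
EX01_S0047	EX01	1	synthetic
EX01_S0048	EX01	1	synthetic
EX01_S0049	EX01	1	synthetic
EX01_S0050	EX01	1	synthetic
EX01_S0051	EX01	1	synthetic
EX01_S0052	EX01	1	synthetic
EX01_S0053	EX01	1	synthetic
EX01_S0054	EX01	1	synthetic
EX01_S0055	EX01	1	synthetic
EX01_S0056	EX01	1	synthetic
EX01_S0057	EX01	1	synthetic
EX01_S0058	EX01	1	synthetic
EX01_S0059	EX01	1	synthetic
EX01_S0060	EX01	1	synthetic
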