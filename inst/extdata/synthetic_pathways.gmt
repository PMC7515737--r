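planted_module	synthetic dense community	g0013	g0016	g0017	g0018	g0019	g0027	g0029	g0032	g0042	g0044	g0053	g0054
random_set_a	synthetic control set	g0044	g0040	g0021	g0002	g0005	g0026	g0056	g0024	g0013	g0007	g0039	star01_leaf03	g0031	g0022	g0058
random_set_b	synthetic control set	g0014	star01_leaf03	g0055	g0033	g0029	g0052	g0019	g0045	g0022	g0040	star01_leaf06	g0036	g0025	g0003	g0046	g0027	star01_leaf05	star01_leaf04	g0057	g0024
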