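# gene	weight
g0001	1.4529
g0002	0.8441
g0003	1.9437
g0004	0.5682
g0005	1.4173
g0006	1.4190
g0007	2.2355
g0008	2.8504
g0009	0.4864
g0010	0.4626
g0011	0.3584
g0012	0.8026
g0013	3.1750
g0014	0.0840
g0015	0.2998
g0016	4.0388
g0017	6.0854
g0018	4.1065
g0019	3.0949
g0020	0.1190
g0021	0.0861
g0022	0.2174
g0023	0.9214
g0024	1.8699
g0025	3.3197
g0026	1.4965
g0027	6.5888
g0028	0.0600
g0029	4.3787
g0030	2.1616
g0031	0.1229
g0032	5.2110
g0033	2.0774
g0034	0.0992
g0035	0.7968
g0036	0.8238
g0037	0.0615
g0038	3.8386
g0039	0.5975
g0040	2.4536
g0041	0.2379
g0042	3.4297
g0043	2.2950
g0044	4.4681
g0045	0.1421
g0046	0.0945
g0047	0.7872
g0048	1.0400
g0049	0.9702
g0050	1.3083
g0051	0.9482
g0052	3.3691
g0053	4.8851
g0054	3.1185
g0055	3.6617
g0056	1.0511
g0057	3.9729
g0058	0.9542
g0059	1.2390
g0060	1.0229
star01_hub	2.5159
star01_leaf01	0.5141
star01_leaf02	0.2059
star01_leaf03	1.5495
star01_leaf04	2.8131
star01_leaf05	0.7350
star01_leaf06	0.2718
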