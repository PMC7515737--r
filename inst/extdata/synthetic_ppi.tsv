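# synthetic interaction network: node1	node2	confidence
g0001	g0002	0.955
g0001	g0003	0.960
g0001	g0007	0.920
g0001	g0021	0.954
g0001	g0022	0.918
g0001	g0025	0.945
g0001	g0031	0.932
g0001	g0039	0.912
g0001	g0042	0.919
g0001	g0043	0.973
g0001	g0049	0.941
g0001	g0058	0.941
g0002	g0003	0.948
g0002	g0004	0.943
g0002	g0005	0.914
g0002	g0006	0.982
g0002	g0010	0.959
g0002	g0012	0.979
g0002	g0014	0.977
g0002	g0016	0.992
g0002	g0047	0.986
g0002	g0048	0.932
g0003	g0004	0.926
g0004	g0005	0.974
g0004	g0006	0.975
g0004	g0007	0.992
g0004	g0008	0.979
g0004	g0009	0.913
g0004	g0011	0.929
g0004	g0022	0.919
g0004	g0032	0.978
g0004	g0036	0.913
g0004	g0039	0.913
g0004	g0044	0.907
g0005	g0008	0.905
g0005	g0013	0.953
g0005	g0017	0.911
g0005	g0040	0.974
g0005	g0041	0.973
g0005	g0050	0.989
g0006	g0009	0.952
g0006	g0013	0.985
g0006	g0018	0.944
g0006	g0020	0.916
g0006	g0024	0.944
g0006	g0029	0.997
g0006	g0033	0.948
g0006	g0037	0.925
g0006	g0038	0.926
g0006	g0047	0.954
g0006	g0054	0.965
g0006	g0055	0.934
g0008	g0016	0.906
g0008	g0026	0.945
g0008	g0029	0.984
g0009	g0010	0.957
g0009	g0024	0.935
g0009	g0030	0.955
g0010	g0011	0.989
g0010	g0045	0.949
g0010	g0048	0.917
g0010	g0052	0.954
g0011	g0012	0.996
g0011	g0023	0.931
g0012	g0014	0.982
g0012	g0015	0.931
g0012	g0019	0.919
g0012	g0020	0.905
g0012	g0042	0.925
g0014	g0015	0.935
g0014	g0017	0.916
g0014	g0018	0.930
g0014	g0019	0.902
g0014	g0027	1.000
g0014	g0028	0.980
g0014	g0033	0.909
g0014	g0035	0.987
g0014	g0040	0.955
g0014	g0055	0.942
g0015	g0021	0.907
g0015	g0043	0.956
g0018	g0032	0.966
g0018	g0046	0.921
g0018	g0060	0.955
g0019	g0023	0.948
g0019	g0034	0.916
g0019	g0044	0.969
g0019	g0052	0.950
g0021	g0030	0.994
g0021	g0031	0.933
g0022	g0038	0.919
g0022	g0058	0.927
g0023	g0027	0.953
g0023	g0035	0.902
g0023	g0045	0.980
g0024	g0025	0.911
g0024	g0026	0.954
g0024	g0041	0.957
g0024	g0049	0.962
g0024	g0053	0.971
g0024	g0054	0.912
g0026	g0028	0.931
g0026	g0059	0.995
g0027	g0036	0.950
g0027	g0037	0.914
g0029	g0046	0.987
g0029	g0051	0.921
g0032	g0053	0.989
g0033	g0034	0.989
g0033	g0057	0.914
g0034	g0057	0.979
g0037	g0060	0.945
g0044	g0050	0.914
g0044	g0051	0.989
g0044	g0059	0.934
g0050	g0056	0.932
g0052	g0056	0.940
g0029	g0042	0.974
g0032	g0044	0.984
g0013	g0027	0.993
g0044	g0053	0.974
g0029	g0044	0.976
g0016	g0029	0.983
g0017	g0054	0.984
g0016	g0042	0.989
g0027	g0044	0.976
g0053	g0054	0.997
g0018	g0042	0.999
g0013	g0018	0.969
g0018	g0053	0.989
g0042	g0054	0.996
g0017	g0044	0.984
g0018	g0019	0.985
g0016	g0027	0.997
g0016	g0044	0.994
g0017	g0053	0.983
g0032	g0054	0.993
g0013	g0032	0.965
g0029	g0032	0.991
g0027	g0032	0.985
g0013	g0019	0.966
g0016	g0018	0.963
g0016	g0019	0.979
g0019	g0042	0.991
g0016	g0017	0.989
g0013	g0054	0.993
g0013	g0016	0.967
g0013	g0053	0.998
g0016	g0053	0.972
g0013	g0044	0.966
g0027	g0053	0.989
g0013	g0029	0.973
g0019	g0054	0.991
g0018	g0044	0.976
star01_hub	star01_leaf01	0.993
star01_hub	star01_leaf02	0.930
star01_hub	star01_leaf03	0.965
star01_hub	star01_leaf04	0.990
star01_hub	star01_leaf05	0.999
star01_hub	star01_leaf06	0.943
g0020	star01_hub	0.939
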