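md	maf	n_snps	f1_loiselle	b_loiselle	r2_loiselle	sp_loiselle	f1_ritland	b_ritland	r2_ritland	sp_ritland	f1_qg	b_qg	r2_qg	sp_qg
0	0.35	256	0.054	-0.033	0.187	0.0352	0.044	-0.033	0.188	0.0350	0.055	-0.074	0.192	0.0780
0	0.30	338	0.053	-0.032	0.191	0.0340	0.043	-0.032	0.190	0.0337	0.054	-0.071	0.197	0.0754
0	0.25	456	0.052	-0.032	0.205	0.0342	0.041	-0.032	0.205	0.0339	0.053	-0.073	0.216	0.0766
0	0.20	537	0.053	-0.034	0.217	0.0355	0.043	-0.034	0.220	0.0355	0.052	-0.073	0.218	0.0771
0	0.15	668	0.053	-0.034	0.217	0.0356	0.044	-0.034	0.215	0.0353	0.052	-0.072	0.212	0.0754
0	0.10	778	0.054	-0.034	0.218	0.0358	0.046	-0.034	0.214	0.0356	0.051	-0.070	0.204	0.0742
0	0.05	829	0.053	-0.033	0.219	0.0351	0.050	-0.032	0.215	0.0341	0.050	-0.072	0.217	0.0755
5	0.35	1011	0.051	-0.032	0.195	0.0336	0.041	-0.032	0.196	0.0334	0.049	-0.069	0.200	0.0726
5	0.30	1090	0.052	-0.032	0.201	0.0338	0.042	-0.032	0.201	0.0335	0.049	-0.068	0.203	0.0717
5	0.25	1406	0.051	-0.032	0.201	0.0338	0.041	-0.032	0.201	0.0336	0.049	-0.069	0.209	0.0726
5	0.20	1721	0.052	-0.033	0.207	0.0346	0.042	-0.033	0.207	0.0344	0.049	-0.069	0.208	0.0729
5	0.15	2099	0.052	-0.033	0.207	0.0343	0.042	-0.033	0.206	0.0340	0.049	-0.069	0.209	0.0716
5	0.10	2492	0.052	-0.033	0.210	0.0344	0.042	-0.033	0.209	0.0340	0.050	-0.070	0.215	0.0715
5	0.05	3029	0.051	-0.032	0.211	0.0336	0.040	-0.031	0.211	0.0324	0.051	-0.071	0.224	0.0726
10	0.35	1352	0.053	-0.033	0.207	0.0351	0.042	-0.033	0.208	0.0348	0.049	-0.070	0.210	0.0738
10	0.30	1777	0.053	-0.033	0.208	0.0348	0.042	-0.033	0.208	0.0345	0.049	-0.069	0.208	0.0729
10	0.25	2267	0.052	-0.033	0.206	0.0347	0.042	-0.033	0.206	0.0343	0.048	-0.069	0.210	0.0713
10	0.20	2753	0.053	-0.033	0.211	0.0353	0.043	-0.034	0.210	0.0350	0.048	-0.068	0.207	0.0720
10	0.15	3342	0.053	-0.033	0.211	0.0350	0.042	-0.033	0.210	0.0346	0.048	-0.068	0.207	0.0721
10	0.10	3884	0.053	-0.033	0.212	0.0350	0.043	-0.033	0.212	0.0346	0.050	-0.069	0.215	0.0722
10	0.05	4666	0.052	-0.032	0.214	0.0342	0.040	-0.032	0.215	0.0329	0.050	-0.070	0.223	0.0732
15	0.35	1630	0.052	-0.033	0.206	0.0351	0.041	-0.033	0.207	0.0348	0.047	-0.069	0.208	0.0735
15	0.30	2159	0.052	-0.033	0.205	0.0348	0.042	-0.033	0.205	0.0345	0.047	-0.068	0.205	0.0729
15	0.25	2748	0.052	-0.033	0.205	0.0347	0.041	-0.033	0.204	0.0344	0.047	-0.068	0.208	0.0717
15	0.20	3324	0.053	-0.033	0.209	0.0353	0.042	-0.034	0.209	0.0350	0.047	-0.068	0.208	0.0722
15	0.15	4022	0.053	-0.033	0.209	0.0350	0.042	-0.033	0.209	0.0346	0.047	-0.068	0.206	0.0716
15	0.10	4675	0.053	-0.033	0.212	0.0350	0.042	-0.033	0.212	0.0346	0.049	-0.069	0.214	0.0712
15	0.05	5569	0.052	-0.032	0.213	0.0342	0.040	-0.032	0.215	0.0329	0.049	-0.067	0.223	0.0718
20	0.35	2042	0.052	-0.033	0.207	0.0352	0.041	-0.033	0.208	0.0348	0.047	-0.068	0.208	0.0705
20	0.30	2675	0.052	-0.033	0.208	0.0351	0.041	-0.033	0.208	0.0347	0.047	-0.068	0.207	0.0725
20	0.25	3388	0.052	-0.033	0.207	0.0351	0.041	-0.033	0.207	0.0348	0.047	-0.068	0.211	0.0716
20	0.20	4088	0.053	-0.034	0.211	0.0357	0.042	-0.034	0.211	0.0354	0.048	-0.069	0.212	0.0722
20	0.15	4959	0.053	-0.034	0.212	0.0354	0.042	-0.034	0.212	0.0350	0.048	-0.068	0.211	0.0717
20	0.10	5762	0.053	-0.033	0.214	0.0353	0.042	-0.033	0.214	0.0348	0.049	-0.069	0.217	0.0729
20	0.05	6898	0.052	-0.033	0.215	0.0344	0.039	-0.032	0.218	0.0330	0.050	-0.070	0.225	0.0735
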