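probe	gene	A_r1	A_r2	A_r3	B_r1	B_r2	B_r3
GENE01_p1	GENE01	9.224	9.501	9.538	8.53	8.3	7.707
GENE01_p2	GENE01	6.825	7.765	7.358	5.99	6.392	6.739
GENE02_p1	GENE02	6.737	6.155	6.199	6.922	7.478	7.203
GENE02_p2	GENE02	6.847	6.909	6.992	7.481	7.759	7.204
GENE03_p1	GENE03	7.508	7.491	7.1	7.413	7.455	7.314
GENE04_p1	GENE04	7.084	6.712	6.552	7.002	6.691	7.255
GENE05_p1	GENE05	10.404	10.676	10.592	8.316	8.906	8.673
GENE06_p1	GENE06	6.427	6.474	6.575	6.927	6.157	6.976
GENE07_p1	GENE07	8.976	9.114	9.213	9.368	8.836	9.344
GENE07_p2	GENE07	7.921	8.097	8.067	7.117	6.676	6.914
GENE08_p1	GENE08	8.461	8.067	8.169	8.45	8.497	8.421
GENE08_p2	GENE08	9.066	9.012	9.665	9.351	9.309	9.257
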