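task	chromosome	objective	method	combination	auroc	auprc	g	sp	sn	tp	fn	tn	fp	n_models
TIS	chr1	-	Std	-	0.9473	0.0929	0.8430	0.9528	0.7458	1608	548	7693177	381413	1
TIS	chr1	AUROC	Cons	Sum	0.9820	0.1529	0.8893	0.9874	0.8010	1727	429	7972989	101601	8
TIS	chr1	AUPRC	Cons	Sum	0.9669	0.1859	0.8326	0.9859	0.7032	1516	640	7960941	113649	29
TIS	chr1	G_MEAN	Cons	Majority	0.9445	0.0074	0.9353	0.9599	0.9114	1965	191	7750802	323788	2
TIS	chr3	-	Std	-	0.9334	0.0831	0.8335	0.9584	0.7248	843	320	6988324	303627	1
TIS	chr3	AUROC	Cons	Sum	0.9761	0.1449	0.8458	0.9929	0.7206	838	325	7240060	51891	8
TIS	chr3	AUPRC	Cons	Sum	0.9596	0.1762	0.7891	0.9920	0.6277	730	433	7233286	58665	33
TIS	chr3	G_MEAN	Cons	Majority	0.9315	0.0049	0.9238	0.9664	0.8831	1027	136	7046822	245129	2
TIS	chr13	-	Std	-	0.9506	0.0844	0.8692	0.9479	0.7971	271	69	3473147	191017	1
TIS	chr13	AUROC	Cons	Sum	0.9778	0.1347	0.8429	0.9940	0.7147	243	97	3642333	21831	7
TIS	chr13	AUPRC	Cons	Sum	0.9692	0.1608	0.7924	0.9929	0.6324	215	125	3638155	26009	28
TIS	chr13	G_MEAN	Cons	Majority	0.9483	0.0038	0.9385	0.9630	0.9147	311	29	3528645	135519	2
TIS	chr19	-	Std	-	0.9456	0.1277	0.8727	0.9068	0.8398	1185	226	1540551	158340	1
TIS	chr19	AUROC	Cons	Sum	0.9716	0.1726	0.8876	0.9691	0.8129	1147	264	1646337	52554	7
TIS	chr19	AUPRC	Cons	Sum	0.9575	0.2048	0.8534	0.9657	0.7541	1064	347	1640628	58263	27
TIS	chr19	G_MEAN	Cons	Majority	0.9436	0.0181	0.9346	0.9555	0.9142	1290	121	1623271	75620	2
TIS	chr21	-	Std	-	0.9353	0.0726	0.8409	0.9415	0.7511	175	58	1227429	76205	1
TIS	chr21	AUROC	Cons	Sum	0.9809	0.1299	0.8612	0.9875	0.7511	175	58	1287377	16257	8
TIS	chr21	AUPRC	Cons	Sum	0.9670	0.1635	0.8201	0.9857	0.6824	159	74	1284991	18643	31
TIS	chr21	G_MEAN	Cons	Majority	0.9362	0.0043	0.9271	0.9582	0.8970	209	24	1249122	54512	2
STOP	chr1	-	Std	-	0.9280	0.0142	0.8487	0.8942	0.8055	1735	419	21077932	2495099	1
STOP	chr1	AUROC	Cons	Sum	0.9705	0.0368	0.8868	0.9707	0.8101	1745	409	22882052	690979	4
STOP	chr1	AUPRC	Cons	Sum	0.9522	0.0525	0.8165	0.9762	0.6829	1471	683	23011801	561230	22
STOP	chr1	G_MEAN	Cons	Majority	0.9307	0.0013	0.9207	0.9426	0.8993	1937	217	22218892	1354139	2
STOP	chr3	-	Std	-	0.9233	0.0083	0.8256	0.9159	0.7442	829	285	19711889	1810611	1
STOP	chr3	AUROC	Cons	Sum	0.9720	0.0262	0.8959	0.9676	0.8294	924	190	20826101	696399	4
STOP	chr3	AUPRC	Cons	Sum	0.9421	0.0297	0.7810	0.9735	0.6266	698	416	20951286	571214	10
STOP	chr3	G_MEAN	Cons	Majority	0.9584	0.0015	0.9128	0.9462	0.8806	981	133	20364397	1158103	4
STOP	chr13	-	Std	-	0.9185	0.0071	0.8150	0.9103	0.7297	243	90	9902079	976223	1
STOP	chr13	AUROC	Cons	Sum	0.9585	0.0156	0.8817	0.9733	0.7988	266	67	10587495	290807	5
STOP	chr13	AUPRC	Cons	Sum	0.9392	0.0311	0.7604	0.9824	0.5886	196	137	10687114	191188	20
STOP	chr13	G_MEAN	Cons	Maximum	0.9502	0.0106	0.8878	0.9545	0.8258	275	58	10383296	495006	6
STOP	chr19	-	Std	-	0.9328	0.0379	0.8515	0.8664	0.8368	1190	232	4042574	623230	1
STOP	chr19	AUROC	Cons	Sum	0.9731	0.0843	0.9160	0.9335	0.8987	1278	144	4355655	310149	5
STOP	chr19	AUPRC	Cons	Sum	0.9557	0.1119	0.8787	0.9250	0.8347	1187	235	4316077	349727	15
STOP	chr19	G_MEAN	Cons	Majority	0.9346	0.0026	0.9169	0.9002	0.9339	1328	94	4199984	465820	2
STOP	chr21	-	Std	-	0.8890	0.0083	0.7778	0.9191	0.6582	156	81	3425375	301584	1
STOP	chr21	AUROC	Cons	Sum	0.9674	0.0383	0.8797	0.9654	0.8017	190	47	3597983	128976	4
STOP	chr21	AUPRC	Cons	Sum	0.9455	0.0382	0.7970	0.9713	0.6540	155	82	3620079	106880	18
STOP	chr21	G_MEAN	Cons	Majority	0.9199	0.0007	0.9087	0.9320	0.8861	210	27	3473463	253496	2
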