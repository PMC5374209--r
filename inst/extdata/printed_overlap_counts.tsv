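# Printed overlap-count rows from the reference tables (2-9). Each row:
# set_a (size n_a), set_b (size n_b), shared members n_common, the printed
# FDR, and the printed percent-of-set_a where one was printed (NA
# otherwise). printed_fdr values depend on the original ~2,000-set
# reference collection and are stored as reference values only.
table	set_a	n_a	set_b	n_b	n_common	printed_fdr	printed_percent	note
T2	HTT Interactome_1619	1619	Exosome Synaptic Rel_892	892	295	2.1E-112	NA	
T2	PerturbDB_1218	1218	Exosome Synaptic Rel_892	892	203	1.5E-62	NA	
T2	HD Common_357	357	Exosome Synaptic Rel_892	892	117	5.9E-70	33	
T2	HTT Interactome_1619	1619	Exosome ProteinDB_4019	4019	832	2.4E-228	51	
T2	PerturbDB_1218	1218	Exosome ProteinDB_4019	4019	512	2.9E-92	42	
T2	HD Common_357	357	Exosome ProteinDB_4019	4019	222	2.7E-79	62	
T3	Mouse R6/2 miRNA changed	80	Exosome miRNA_755	755	49	NA	61	
T3	Mouse YAC128 miRNA changed	79	Exosome miRNA_755	755	52	NA	66	
T3	Human HD Cortex miRNA changed	158	Exosome miRNA_755	755	79	NA	50	
T3	Human HD Caudate miRNA changed	131	Exosome miRNA_755	755	66	NA	50	
T4	HTT Interactome_1619	1619	HmSP Functional Set_143	143	46	8.2E-18	3	
T4	PerturbDB_1218	1218	HmSP Functional Set_143	143	49	2.4E-25	4	
T4	HD Common_357	357	HmSP Functional Set_143	143	24	9.6E-19	7	
T5	HTT Interactome_1619	1619	HmSP DB_3782	3782	825	5.6E-243	51	
T5	PerturbDB_1218	1218	HmSP DB_3782	3782	583	1.7E-151	48	
T5	HD Common_357	357	HmSP DB_3782	3782	254	1.9E-117	71	
T5	HTT Interactome_1619	1619	Exosome DB_4469	4469	931	4.8E-270	NA	
T5	PerturbDB_1218	1218	Exosome DB_4469	4469	593	9.2E-120	NA	
T5	HD Common_357	357	Exosome DB_4469	4469	265	1.8E-108	NA	
T5	HTT Interactome_1619	1619	HmSP-Exosome Common_1600	1600	586	1.3E-287	NA	
T5	PerturbDB_1218	1218	HmSP-Exosome Common_1600	1600	356	3.3E-132	NA	
T5	HD Common_357	357	HmSP-Exosome Common_1600	1600	202	4.3E-139	NA	
T6	PD Set_763	763	HTT Interactome_1619	1619	370	5.4E-224	48	
T6	SNCA PPI_398	398	HTT Interactome_1619	1619	235	9.7E-165	59	
T6	LRRK2 PPI_198	198	HTT Interactome_1619	1619	108	3.2E-69	55	
T6	PARK7 PPI_147	147	HTT Interactome_1619	1619	73	6.0E-43	50	
T6	PARK2 PPI_176	176	HTT Interactome_1619	1619	77	2.7E-40	44	
T6	PINK1 PPI_52	52	HTT Interactome_1619	1619	25	1.2E-14	48	
T6	AD Set_2354	2354	HTT Interactome_1619	1619	400	1.1E-65	17	
T6	MAPT PPI_118	118	HTT Interactome_1619	1619	67	2.2E-44	57	
T6	PSEN1|2 PPI_253	253	HTT Interactome_1619	1619	97	1.2E-44	38	
T6	APP PPI_2133	2133	HTT Interactome_1619	1619	310	3.3E-35	15	
T6	PolyQ Set_1139	1139	HTT Interactome_1619	1619	303	2.1E-96	27	
T6	CACNA1A PPI_215	215	HTT Interactome_1619	1619	87	3.1E-42	40	
T6	ATXN3 PPI_98	98	HTT Interactome_1619	1619	44	1.0E-23	45	
T6	ATXN2 PPI_51	51	HTT Interactome_1619	1619	21	7.6E-11	41	
T6	ATXN1 PPI_272	272	HTT Interactome_1619	1619	74	2.7E-23	27	
T6	AR PPI_325	325	HTT Interactome_1619	1619	86	4.3E-26	26	
T6	TBP PPI_246	246	HTT Interactome_1619	1619	57	1.0E-14	23	
T6	ATXN7 PPI_87	87	HTT Interactome_1619	1619	23	1.5E-07	26	
T6	ATN1 PPI_115	115	HTT Interactome_1619	1619	28	3.7E-08	24	
T6	ALS Set_328	328	HTT Interactome_1619	1619	123	1.7E-55	38	
T6	SOD1 PPI_84	84	HTT Interactome_1619	1619	36	1.0E-18	43	
T6	TARDBP PPI_120	120	HTT Interactome_1619	1619	46	2.5E-21	38	
T6	FUS PPI_159	159	HTT Interactome_1619	1619	54	5.0E-22	34	
T6	SMA SMN1|2 PPI_241	241	HTT Interactome_1619	1619	67	1.10E-21	28	
T7	PD_PPI_763	763	HTT Interactome_1619	1619	370	5.4E-224	NA	
T7	PD_PPI_763	763	PerturbDB_1218	1218	232	2.5E-111	NA	
T7	PD_PPI_763	763	HD Common_357	357	150	5.8E-124	NA	
T7	PolyQ_PPI_1139	1139	HTT Interactome_1619	1619	303	2.1E-96	NA	
T7	PolyQ_PPI_1139	1139	PerturbDB_1218	1218	220	3.2E-64	NA	
T7	PolyQ_PPI_1139	1139	HD Common_357	357	113	3.0E-57	NA	
T7	AD_PPI_2354	2354	HTT Interactome_1619	1619	400	1.1E-65	NA	
T7	AD_PPI_2354	2354	PerturbDB_1218	1218	280	4.2E-38	NA	
T7	AD_PPI_2354	2354	HD Common_357	357	127	6.2E-36	NA	
T7	ALS_PPI_328	328	HTT Interactome_1619	1619	123	1.7E-55	NA	
T7	ALS_PPI_328	328	PerturbDB_1218	1218	80	1.2E-29	NA	
T7	ALS_PPI_328	328	HD Common_357	357	47	1.5E-29	NA	
T7	SMA_PPI_241	241	HTT Interactome_1619	1619	67	1.1E-21	NA	
T7	SMA_PPI_241	241	PerturbDB_1218	1218	48	2.4E-14	NA	
T7	SMA_PPI_241	241	HD Common_357	357	23	7.7E-11	NA	
T8	PD PPI_763	763	HmSP DB_3782	3782	480	4.9E-187	63	
T8	PD PPI_763	763	Exosomes DB_4469	4469	494	2.7E-167	65	
T8	PD PPI_763	763	HmSP Exosome Common_1600	1600	354	1.2E-206	46	
T8	PolyQ PPI_1139	1139	HmSP DB_3782	3782	736	1.4E-306	65	
T8	PolyQ PPI_1139	1139	Exosomes DB_4469	4469	440	6.3E-51	39	
T8	PolyQ PPI_1139	1139	HmSP Exosome Common_1600	1600	349	2.5E-134	31	
T8	AD PPI_2354	2354	HmSP DB_3782	3782	861	4.2E-135	37	
T8	AD PPI_2354	2354	Exosomes DB_4469	4469	824	6.4E-75	35	
T8	AD PPI_2354	2354	HmSP Exosome Common_1600	1600	473	1.8E-108	20	
T8	ALS PPI_328	328	HmSP DB_3782	3782	229	1.1E-100	70	
T8	ALS PPI_328	328	Exosomes DB_4469	4469	203	1.3E-61	62	
T8	ALS PPI_328	328	HmSP Exosome Common_1600	1600	162	8.5E-96	49	
T9	HTT Interactome_1619	1619	Synaptic Localized Transcripts_2305	2305	436	1.31E-87	27	
T9	PerturbDB Total_1218	1218	Synaptic Localized Transcripts_2305	2305	282	1.98E-40	23	
T9	HD Common_357	357	Synaptic Localized Transcripts_2305	2305	113	1.55E-27	31	printed percent inconsistent with counts
T9	PD All PPI_763	763	Synaptic Localized Transcripts_2305	2305	177	2.13E-25	23	
T9	PD +HTT PPI_371	371	Synaptic Localized Transcripts_2305	2305	111	3.49E-25	30	
T9	PolyQ All PPI_1139	1139	Synaptic Localized Transcripts_2305	2305	223	1.99E-21	20	
T9	PolyQ +HTT PPI_303	303	Synaptic Localized Transcripts_2305	2305	86	7.79E-18	28	
T9	AD All PPI_2354	2354	Synaptic Localized Transcripts_2305	2305	404	7.92E-27	17	
T9	AD +HTT PPI_400	400	Synaptic Localized Transcripts_2305	2305	119	1.39E-26	30	
T9	ALS All PPI_328	328	Synaptic Localized Transcripts_2305	2305	88	2.13E-16	27	
T9	ALS +HTT PPI_123	123	Synaptic Localized Transcripts_2305	2305	44	6.85E-13	36	
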