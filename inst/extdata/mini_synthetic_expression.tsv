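gene_id	S0001	S0002	S0003	S0004	S0005	S0006	S0007	S0008	S0009	S0010	S0011	S0012	S0013	S0014	S0015	S0016	S0017	S0018	S0019	S0020	S0021	S0022	S0023	S0024
LNC0001	259	343	276	485	834	396	757	304	330	242	210	0	559	167	549	882	908	0	246	308	137	980	456	433
LNC0002	28	4	19	45	10	24	10	13	13	11	73	18	21	26	18	24	24	6	30	10	21	29	29	29
LNC0003	10	34	19	17	41	39	18	23	18	14	69	6	57	53	31	27	34	20	24	16	41	21	15	12
LNC0004	32	42	60	80	46	46	68	88	45	55	121	62	52	114	40	140	108	89	54	41	46	61	67	59
LNC0005	458	284	363	262	395	286	390	331	343	308	558	245	315	472	446	601	654	416	378	369	420	478	378	482
LNC0006	179	131	220	161	203	158	200	258	110	77	211	126	155	172	129	210	211	101	126	118	88	203	172	127
LNC0007	87	16	28	70	46	53	45	21	55	45	54	51	45	48	16	34	63	22	29	49	29	53	13	25
LNC0008	79	62	42	58	41	36	40	20	24	31	80	44	50	105	41	136	58	41	64	20	48	50	44	38
PCG0001	57	11	22	65	56	27	40	39	30	52	70	49	68	46	23	50	92	22	62	31	66	53	25	52
PCG0002	239	82	110	178	179	91	142	186	90	74	221	47	75	149	178	281	237	71	95	78	90	159	206	99
PCG0003	55	64	74	85	73	33	84	45	84	70	92	22	67	137	48	81	118	58	110	31	48	92	85	62
PCG0004	29	16	15	20	15	24	13	11	12	9	26	6	7	12	18	8	12	11	11	18	6	31	6	13
PCG0005	16	22	17	30	7	41	22	7	20	23	11	25	29	51	15	35	45	35	24	6	13	37	15	22
PCG0006	47	26	75	22	53	43	22	22	23	41	70	25	40	32	65	48	69	25	78	27	22	23	43	60
PCG0007	79	86	170	162	92	112	149	202	108	87	152	90	123	239	127	243	143	137	152	102	123	129	172	131
PCG0008	130	87	110	181	65	120	92	126	79	79	119	131	121	87	179	130	110	64	174	110	86	124	38	98
PCG0009	19	17	27	59	16	41	22	35	38	29	52	25	42	69	55	73	16	19	21	45	19	21	14	35
PCG0010	337	392	349	414	260	430	315	306	345	251	490	325	364	344	409	445	670	394	257	440	484	301	306	322
PCG0011	145	95	101	121	64	106	76	79	104	42	241	102	92	75	85	119	199	52	66	124	91	142	94	128
PCG0012	96	33	128	105	75	110	102	108	142	106	115	56	128	91	62	124	109	74	75	124	82	123	47	92
PCG0013	46	41	84	84	105	112	134	32	60	58	98	66	73	86	126	98	97	36	93	66	57	92	111	67
PCG0014	1440	1044	1202	1185	876	1090	1138	1209	808	727	1589	1051	1585	1547	881	1934	1402	1226	1450	595	944	1870	1266	1187
PCG0015	205	79	95	258	91	111	115	159	95	88	157	124	70	160	112	152	195	93	113	138	148	219	131	146
PCG0016	32	72	70	80	96	88	96	62	76	65	103	46	35	92	58	87	77	42	66	34	87	52	60	74
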