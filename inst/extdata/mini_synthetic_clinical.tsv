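Sample_ID	Survival_Time	Status	age
S0001	1226.141727487457	1	79
S0002	1427.0667184316344	1	36
S0003	2358.2057038924459	1	63
S0004	230.98181560635567	1	55
S0005	869.56664636255516	1	75
S0006	136.04013771598264	1	51
S0007	100.05520691077336	1	56
S0008	218.03931792746968	0	51
S0009	261.13295322284102	1	61
S0010	756.51941351116909	1	49
S0011	819.85783138863644	1	66
S0012	844.12926223375177	1	79
S0013	918.44210405145748	0	76
S0014	351.01365790058281	0	58
S0015	226.12371129596136	1	83
S0016	1067.9492307406786	1	80
S0017	706.25990159333958	1	81
S0018	333.01900699734688	1	71
S0019	1397.2202644787358	0	81
S0020	2505.2411238333943	1	58
S0021	1982.5380145663264	1	75
S0022	202.68430798850605	0	41
S0023	1298.3762762694348	0	72
S0024	164.29079769898587	1	61
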