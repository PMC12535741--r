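feature_id	S0001	S0002	S0003	S0004	S0005	S0006	S0007	S0008	S0009	S0010	S0011	S0012	S0013	S0014	S0015	S0016	S0017	S0018	S0019	S0020	S0021	S0022	S0023	S0024
LNC0001	2	3	1	2	4	3	3	2	3	2	1	0	3	1	3	3	3	0	1	2	1	3	3	4
LNC0002	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2
LNC0003	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2
LNC0004	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2
LNC0005	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2
LNC0006	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2
LNC0007	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2
LNC0008	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2
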