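mirna	gene	score	rank	n_sources	rank_source1	rank_source2	rank_source3	rank_source4
hsa-miR-002-5p	G000022	0.014505	1	2	1		2	
hsa-miR-002-5p	G000068	0.037304	2	4	33	2	11	10
hsa-miR-002-5p	G000006	0.056075	3	2	2		4	
hsa-miR-001-5p	G000044	0.086121	4	3		5	1	36
hsa-miR-002-5p	G000004	0.130502	5	4	21	33	20	34
hsa-miR-001-5p	G000064	0.196281	6	4	55	1	46	20
hsa-miR-001-5p	G000077	0.196281	7	3	47	26		1
hsa-miR-002-5p	G000020	0.260110	8	3		6	78	9
hsa-miR-002-5p	G000046	0.260110	9	3	9		7	61
hsa-miR-002-5p	G000056	0.264120	10	4	3	22	43	22
hsa-miR-001-5p	G000048	0.275953	11	4	11	41	5	37
hsa-miR-002-5p	G000091	0.298234	12	4	71	23	21	5
hsa-miR-001-5p	G000093	0.303877	13	4	42	21	33	42
hsa-miR-001-5p	G000100	0.315430	14	4	73	10	8	78
hsa-miR-002-5p	G000023	0.315430	15	4	10	60	70	7
hsa-miR-001-5p	G000057	0.385248	16	3	63	54		2
hsa-miR-001-5p	G000050	0.438075	17	2	12		6	
hsa-miR-002-5p	G000052	0.476531	18	4	45	3	47	38
hsa-miR-002-5p	G000028	0.504805	19	3	13	79	10	
hsa-miR-001-5p	G000021	0.518400	20	4	7	17	40	48
hsa-miR-002-5p	G000075	0.567086	21	4	58	27	3	47
hsa-miR-002-5p	G000089	0.567086	22	2	49			3
hsa-miR-001-5p	G000026	0.606445	23	3	19		30	6
hsa-miR-001-5p	G000018	0.723200	24	4	38	16	63	12
hsa-miR-002-5p	G000037	0.741975	25	4	4	25	67	60
hsa-miR-002-5p	G000014	0.741975	26	3	40	4	68	
hsa-miR-002-5p	G000029	0.741975	27	3	30	44		4
hsa-miR-001-5p	G000053	0.770555	28	4	51	53	25	11
hsa-miR-002-5p	G000063	0.910095	29	2	5			70
hsa-miR-002-5p	G000017	0.963242	30	3	17	19	65	
hsa-miR-001-5p	G000003	1.000000	31	4	52	37	12	73
hsa-miR-001-5p	G000005	1.000000	32	4	34	61	42	79
hsa-miR-001-5p	G000033	1.000000	33	4	18	66	72	43
hsa-miR-001-5p	G000041	1.000000	34	4	75	38	62	51
hsa-miR-001-5p	G000045	1.000000	35	4	46	69	14	27
hsa-miR-001-5p	G000051	1.000000	36	4	80	12	80	23
hsa-miR-001-5p	G000059	1.000000	37	4	22	57	51	15
hsa-miR-001-5p	G000060	1.000000	38	4	67	24	64	19
hsa-miR-001-5p	G000073	1.000000	39	4	78	52	79	26
hsa-miR-001-5p	G000080	1.000000	40	4	61	20	56	21
hsa-miR-002-5p	G000001	1.000000	41	4	79	49	26	57
hsa-miR-002-5p	G000010	1.000000	42	4	60	77	34	33
hsa-miR-002-5p	G000032	1.000000	43	4	48	72	53	59
hsa-miR-002-5p	G000034	1.000000	44	4	23	59	15	49
hsa-miR-002-5p	G000039	1.000000	45	4	8	46	58	29
hsa-miR-002-5p	G000040	1.000000	46	4	20	76	27	63
hsa-miR-002-5p	G000043	1.000000	47	4	27	56	13	68
hsa-miR-002-5p	G000061	1.000000	48	4	66	39	9	76
hsa-miR-002-5p	G000065	1.000000	49	4	54	70	24	66
hsa-miR-002-5p	G000087	1.000000	50	4	56	67	54	32
hsa-miR-002-5p	G000094	1.000000	51	4	57	14	73	56
hsa-miR-002-5p	G000099	1.000000	52	4	59	34	61	69
hsa-miR-001-5p	G000002	1.000000	53	3	68	11		28
hsa-miR-001-5p	G000012	1.000000	54	3	74		41	75
hsa-miR-001-5p	G000016	1.000000	55	3	15	43	77	
hsa-miR-001-5p	G000025	1.000000	56	3		80	49	18
hsa-miR-001-5p	G000030	1.000000	57	3	37	58		13
hsa-miR-001-5p	G000031	1.000000	58	3	16	30		65
hsa-miR-001-5p	G000036	1.000000	59	3	41	75		35
hsa-miR-001-5p	G000049	1.000000	60	3		65	60	53
hsa-miR-001-5p	G000054	1.000000	61	3		78	31	62
hsa-miR-001-5p	G000058	1.000000	62	3	32		44	64
hsa-miR-001-5p	G000067	1.000000	63	3	36		59	55
hsa-miR-001-5p	G000076	1.000000	64	3		28	55	40
hsa-miR-001-5p	G000081	1.000000	65	3	35	64	19	
hsa-miR-001-5p	G000082	1.000000	66	3	39	32	52	
hsa-miR-001-5p	G000086	1.000000	67	3	50	63		30
hsa-miR-001-5p	G000096	1.000000	68	3	77		37	67
hsa-miR-002-5p	G000008	1.000000	69	3	43	29	74	
hsa-miR-002-5p	G000015	1.000000	70	3	31		75	16
hsa-miR-002-5p	G000019	1.000000	71	3		18	45	41
hsa-miR-002-5p	G000024	1.000000	72	3	69		28	77
hsa-miR-002-5p	G000027	1.000000	73	3		68	48	24
hsa-miR-002-5p	G000035	1.000000	74	3	26	45	57	
hsa-miR-002-5p	G000038	1.000000	75	3	62		23	72
hsa-miR-002-5p	G000047	1.000000	76	3		74	36	50
hsa-miR-002-5p	G000055	1.000000	77	3		50	16	71
hsa-miR-002-5p	G000066	1.000000	78	3		51	35	80
hsa-miR-002-5p	G000069	1.000000	79	3		55	17	44
hsa-miR-002-5p	G000078	1.000000	80	3	70	47		14
hsa-miR-002-5p	G000079	1.000000	81	3		42	50	58
hsa-miR-002-5p	G000083	1.000000	82	3	29	48	76	
hsa-miR-002-5p	G000084	1.000000	83	3	53	13	39	
hsa-miR-002-5p	G000085	1.000000	84	3	6		71	45
hsa-miR-002-5p	G000090	1.000000	85	3	76	71		17
hsa-miR-002-5p	G000092	1.000000	86	3	64	35		31
hsa-miR-002-5p	G000095	1.000000	87	3	25	31		39
hsa-miR-002-5p	G000097	1.000000	88	3		8	29	46
hsa-miR-001-5p	G000007	1.000000	89	2	14		69	
hsa-miR-002-5p	G000009	1.000000	90	2		7		52
hsa-miR-002-5p	G000011	1.000000	91	2	72	73		
hsa-miR-002-5p	G000013	1.000000	92	2		15		74
hsa-miR-002-5p	G000042	1.000000	93	2	65		66	
hsa-miR-002-5p	G000062	1.000000	94	2		62	32	
hsa-miR-002-5p	G000070	1.000000	95	2	44			25
hsa-miR-002-5p	G000071	1.000000	96	2	28			54
hsa-miR-002-5p	G000072	1.000000	97	2		9	22	
hsa-miR-002-5p	G000074	1.000000	98	2	24			8
hsa-miR-002-5p	G000088	1.000000	99	2		40	38	
hsa-miR-002-5p	G000098	1.000000	100	2		36	18	
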