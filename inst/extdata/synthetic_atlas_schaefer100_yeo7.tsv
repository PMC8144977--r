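parcel_id	network	hemisphere	subroi
1	Vis	L	NA
2	Vis	L	NA
3	Vis	L	NA
4	Vis	L	NA
5	Vis	L	NA
6	Vis	L	NA
7	Vis	L	NA
8	SomMot	L	NA
9	SomMot	L	NA
10	SomMot	L	NA
11	SomMot	L	NA
12	SomMot	L	NA
13	SomMot	L	NA
14	SomMot	L	NA
15	SomMot	L	NA
16	DorsAttn	L	NA
17	DorsAttn	L	NA
18	DorsAttn	L	NA
19	DorsAttn	L	NA
20	DorsAttn	L	NA
21	DorsAttn	L	NA
22	DorsAttn	L	NA
23	SalVentAttn	L	TPJ
24	SalVentAttn	L	TPJ
25	SalVentAttn	L	NA
26	SalVentAttn	L	NA
27	SalVentAttn	L	NA
28	SalVentAttn	L	NA
29	Limbic	L	NA
30	Limbic	L	NA
31	Limbic	L	NA
32	Limbic	L	NA
33	Limbic	L	NA
34	Cont	L	NA
35	Cont	L	NA
36	Cont	L	NA
37	Cont	L	NA
38	Cont	L	NA
39	Cont	L	NA
40	Default	L	NA
41	Default	L	NA
42	Default	L	NA
43	Default	L	NA
44	Default	L	NA
45	Default	L	NA
46	Default	L	NA
47	Default	L	NA
48	Default	L	NA
49	Default	L	NA
50	Default	L	NA
51	Vis	R	NA
52	Vis	R	NA
53	Vis	R	NA
54	Vis	R	NA
55	Vis	R	NA
56	Vis	R	NA
57	Vis	R	NA
58	SomMot	R	NA
59	SomMot	R	NA
60	SomMot	R	NA
61	SomMot	R	NA
62	SomMot	R	NA
63	SomMot	R	NA
64	SomMot	R	NA
65	SomMot	R	NA
66	DorsAttn	R	NA
67	DorsAttn	R	NA
68	DorsAttn	R	NA
69	DorsAttn	R	NA
70	DorsAttn	R	NA
71	DorsAttn	R	NA
72	DorsAttn	R	NA
73	SalVentAttn	R	TPJ
74	SalVentAttn	R	TPJ
75	SalVentAttn	R	NA
76	SalVentAttn	R	NA
77	SalVentAttn	R	NA
78	SalVentAttn	R	NA
79	Limbic	R	NA
80	Limbic	R	NA
81	Limbic	R	NA
82	Limbic	R	NA
83	Limbic	R	NA
84	Cont	R	NA
85	Cont	R	NA
86	Cont	R	NA
87	Cont	R	NA
88	Cont	R	NA
89	Cont	R	NA
90	Default	R	NA
91	Default	R	NA
92	Default	R	NA
93	Default	R	NA
94	Default	R	NA
95	Default	R	NA
96	Default	R	NA
97	Default	R	NA
98	Default	R	NA
99	Default	R	NA
100	Default	R	NA
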