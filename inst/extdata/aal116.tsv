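index	short_name	full_name	lobe	cerebellum
1	PreCG.L	Precentral gyrus left	Frontal	0
2	PreCG.R	Precentral gyrus right	Frontal	0
3	SFGdor.L	Superior frontal gyrus, dorsolateral left	Frontal	0
4	SFGdor.R	Superior frontal gyrus, dorsolateral right	Frontal	0
5	ORBsup.L	Superior frontal gyrus, orbital part left	Frontal	0
6	ORBsup.R	Superior frontal gyrus, orbital part right	Frontal	0
7	MFG.L	Middle frontal gyrus left	Frontal	0
8	MFG.R	Middle frontal gyrus right	Frontal	0
9	ORBmid.L	Middle frontal gyrus, orbital part left	Frontal	0
10	ORBmid.R	Middle frontal gyrus, orbital part right	Frontal	0
11	IFGoperc.L	Inferior frontal gyrus, opercular part left	Frontal	0
12	IFGoperc.R	Inferior frontal gyrus, opercular part right	Frontal	0
13	IFGtriang.L	Inferior frontal gyrus, triangular part left	Frontal	0
14	IFGtriang.R	Inferior frontal gyrus, triangular part right	Frontal	0
15	ORBinf.L	Inferior frontal gyrus, orbital part left	Frontal	0
16	ORBinf.R	Inferior frontal gyrus, orbital part right	Frontal	0
17	ROL.L	Rolandic operculum left	Frontal	0
18	ROL.R	Rolandic operculum right	Frontal	0
19	SMA.L	Supplementary motor area left	Frontal	0
20	SMA.R	Supplementary motor area right	Frontal	0
21	OLF.L	Olfactory cortex left	Frontal	0
22	OLF.R	Olfactory cortex right	Frontal	0
23	SFGmed.L	Superior frontal gyrus, medial left	Frontal	0
24	SFGmed.R	Superior frontal gyrus, medial right	Frontal	0
25	ORBsupmed.L	Superior frontal gyrus, medial orbital left	Frontal	0
26	ORBsupmed.R	Superior frontal gyrus, medial orbital right	Frontal	0
27	REC.L	Gyrus rectus left	Frontal	0
28	REC.R	Gyrus rectus right	Frontal	0
29	INS.L	Insula left	Insula	0
30	INS.R	Insula right	Insula	0
31	ACG.L	Anterior cingulate and paracingulate gyri left	Limbic	0
32	ACG.R	Anterior cingulate and paracingulate gyri right	Limbic	0
33	DCG.L	Median cingulate and paracingulate gyri left	Limbic	0
34	DCG.R	Median cingulate and paracingulate gyri right	Limbic	0
35	PCG.L	Posterior cingulate gyrus left	Limbic	0
36	PCG.R	Posterior cingulate gyrus right	Limbic	0
37	HIP.L	Hippocampus left	Limbic	0
38	HIP.R	Hippocampus right	Limbic	0
39	PHG.L	Parahippocampal gyrus left	Limbic	0
40	PHG.R	Parahippocampal gyrus right	Limbic	0
41	AMYG.L	Amygdala left	Limbic	0
42	AMYG.R	Amygdala right	Limbic	0
43	CAL.L	Calcarine fissure and surrounding cortex left	Occipital	0
44	CAL.R	Calcarine fissure and surrounding cortex right	Occipital	0
45	CUN.L	Cuneus left	Occipital	0
46	CUN.R	Cuneus right	Occipital	0
47	LING.L	Lingual gyrus left	Occipital	0
48	LING.R	Lingual gyrus right	Occipital	0
49	SOG.L	Superior occipital gyrus left	Occipital	0
50	SOG.R	Superior occipital gyrus right	Occipital	0
51	MOG.L	Middle occipital gyrus left	Occipital	0
52	MOG.R	Middle occipital gyrus right	Occipital	0
53	IOG.L	Inferior occipital gyrus left	Occipital	0
54	IOG.R	Inferior occipital gyrus right	Occipital	0
55	FFG.L	Fusiform gyrus left	Temporal	0
56	FFG.R	Fusiform gyrus right	Temporal	0
57	PoCG.L	Postcentral gyrus left	Parietal	0
58	PoCG.R	Postcentral gyrus right	Parietal	0
59	SPG.L	Superior parietal gyrus left	Parietal	0
60	SPG.R	Superior parietal gyrus right	Parietal	0
61	IPL.L	Inferior parietal lobule left	Parietal	0
62	IPL.R	Inferior parietal lobule right	Parietal	0
63	SMG.L	Supramarginal gyrus left	Parietal	0
64	SMG.R	Supramarginal gyrus right	Parietal	0
65	ANG.L	Angular gyrus left	Parietal	0
66	ANG.R	Angular gyrus right	Parietal	0
67	PCUN.L	Precuneus left	Parietal	0
68	PCUN.R	Precuneus right	Parietal	0
69	PCL.L	Paracentral lobule left	Frontal	0
70	PCL.R	Paracentral lobule right	Frontal	0
71	CAU.L	Caudate nucleus left	Subcortical	0
72	CAU.R	Caudate nucleus right	Subcortical	0
73	PUT.L	Lenticular nucleus, putamen left	Subcortical	0
74	PUT.R	Lenticular nucleus, putamen right	Subcortical	0
75	PAL.L	Lenticular nucleus, pallidum left	Subcortical	0
76	PAL.R	Lenticular nucleus, pallidum right	Subcortical	0
77	THA.L	Thalamus left	Subcortical	0
78	THA.R	Thalamus right	Subcortical	0
79	HES.L	Heschl gyrus left	Temporal	0
80	HES.R	Heschl gyrus right	Temporal	0
81	STG.L	Superior temporal gyrus left	Temporal	0
82	STG.R	Superior temporal gyrus right	Temporal	0
83	TPOsup.L	Temporal pole: superior temporal gyrus left	Temporal	0
84	TPOsup.R	Temporal pole: superior temporal gyrus right	Temporal	0
85	MTG.L	Middle temporal gyrus left	Temporal	0
86	MTG.R	Middle temporal gyrus right	Temporal	0
87	TPOmid.L	Temporal pole: middle temporal gyrus left	Temporal	0
88	TPOmid.R	Temporal pole: middle temporal gyrus right	Temporal	0
89	ITG.L	Inferior temporal gyrus left	Temporal	0
90	ITG.R	Inferior temporal gyrus right	Temporal	0
91	CRBLCrus1.L	Cerebellum Crus1 left	Cerebellum	1
92	CRBLCrus1.R	Cerebellum Crus1 right	Cerebellum	1
93	CRBLCrus2.L	Cerebellum Crus2 left	Cerebellum	1
94	CRBLCrus2.R	Cerebellum Crus2 right	Cerebellum	1
95	CRBL3.L	Cerebellum 3 left	Cerebellum	1
96	CRBL3.R	Cerebellum 3 right	Cerebellum	1
97	CRBL4_5.L	Cerebellum 4_5 left	Cerebellum	1
98	CRBL4_5.R	Cerebellum 4_5 right	Cerebellum	1
99	CRBL6.L	Cerebellum 6 left	Cerebellum	1
100	CRBL6.R	Cerebellum 6 right	Cerebellum	1
101	CRBL7b.L	Cerebellum 7b left	Cerebellum	1
102	CRBL7b.R	Cerebellum 7b right	Cerebellum	1
103	CRBL8.L	Cerebellum 8 left	Cerebellum	1
104	CRBL8.R	Cerebellum 8 right	Cerebellum	1
105	CRBL9.L	Cerebellum 9 left	Cerebellum	1
106	CRBL9.R	Cerebellum 9 right	Cerebellum	1
107	CRBL10.L	Cerebellum 10 left	Cerebellum	1
108	CRBL10.R	Cerebellum 10 right	Cerebellum	1
109	Vermis1_2	Vermis 1_2	Cerebellum	1
110	Vermis3	Vermis 3	Cerebellum	1
111	Vermis4_5	Vermis 4_5	Cerebellum	1
112	Vermis6	Vermis 6	Cerebellum	1
113	Vermis7	Vermis 7	Cerebellum	1
114	Vermis8	Vermis 8	Cerebellum	1
115	Vermis9	Vermis 9	Cerebellum	1
116	Vermis10	Vermis 10	Cerebellum	1
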