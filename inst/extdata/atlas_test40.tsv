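node_id	node_name	network	hemisphere
1	L_FPN_001	FPN	L
2	R_CO_001	CO	R
3	L_CO_001	CO	L
4	R_DMN_001	DMN	R
5	L_DAN_001	DAN	L
6	R_FPN_001	FPN	R
7	L_Visual_001	Visual	L
8	R_DAN_001	DAN	R
9	L_DMN_001	DMN	L
10	R_DMN_002	DMN	R
11	L_Visual_002	Visual	L
12	R_CO_002	CO	R
13	L_Visual_003	Visual	L
14	R_DAN_002	DAN	R
15	L_CO_002	CO	L
16	R_DAN_003	DAN	R
17	L_CO_003	CO	L
18	R_DMN_003	DMN	R
19	L_Visual_004	Visual	L
20	R_DMN_004	DMN	R
21	L_SAL_001	SAL	L
22	R_FPN_002	FPN	R
23	L_DMN_002	DMN	L
24	R_SAL_001	SAL	R
25	L_CO_004	CO	L
26	R_DAN_004	DAN	R
27	L_CO_005	CO	L
28	R_Visual_001	Visual	R
29	L_SAL_002	SAL	L
30	R_SAL_002	SAL	R
31	L_FPN_002	FPN	L
32	R_CO_003	CO	R
33	L_FPN_003	FPN	L
34	R_SAL_003	SAL	R
35	L_DMN_003	DMN	L
36	R_FPN_003	FPN	R
37	L_caudate	subcortical	subcortical
38	R_caudate	subcortical	subcortical
39	L_thalamus	subcortical	subcortical
40	R_thalamus	subcortical	subcortical
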