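gene_id	E1-25DA-M	E2-25DA-M	E3-25DC-M	E4-25DC-M	E5-25DC-M	E6-25DC-M	E7-25DC-M	F1-35DC-M	F2-35DC-M	F3-35DC-M	F4-35DA-M	F5-35DA-M	F6-35DA-M	F7-35DA-M	F8-35DC-M	F9-35DA-M	F10-35DA-M	E1-25DA-F	E2-25DA-F	E3-25DC-F	E4-25DC-F	E5-25DC-F	E6-25DC-F	E7-25DC-F	E8-25DC-F	E9-25DC-F	E10-25DC-F	E11-25DA-F	F1-35DA-F	F2-35DA-F	F3-35DA-F	F4-35DC-F	F5-35DA-F	F6-35DA-F	F7-35DA-F
DDX3Y	151.46	166.54	167.21	170.76	149.28	156.64	166.1	193.41	167.28	168.09	157.51	200.33	187.01	180.78	178.15	143.33	173.51	0	0	0	0.28	0	0	0	0	0	0	0.13	0.08	0	0.16	0	0.71	0.22	0
KDM5D	7.52	7.64	9.56	10.15	6.56	9.19	9.43	5.35	7.11	7.05	8.17	8.04	6.47	7.06	10.68	10.28	10.4	0.07	0	0	0	0	0	0	0	0	0	0	0	0.08	0	0	0	0.07	0
ZFY	24.81	31.68	28.67	29.78	24.94	30.92	33.57	26.07	28.43	31.32	26.77	24.02	24.02	29.27	33.04	27.83	26.69	0	0	0.07	0.07	0	0.14	0.15	0	0	0.08	0.07	0.08	0.23	0	0.07	0.32	0.14	0.07
EIF2S3Y	162.23	197.73	211.97	189.79	180.78	192.23	192.23	130.67	135.38	141.53	119.45	126.13	128.61	133.42	155.57	135.33	128.32	0	0	0.07	0.07	0.15	0	0.08	0	0	0.08	0.13	0	0	0.25	0	0.48	0.29	0
EIF1AY	40.64	45.16	45.86	46.39	36.55	40.76	44.92	44.65	39.84	37.8	33.45	45.09	41.58	41.14	43.49	31.42	36.71	0.07	0.07	0	0.07	0	0.07	0	0	0.07	0.08	0.07	0	0.08	0.08	0	0.08	0.07	0
LOC110255320	12.04	12.3	13.23	11.43	13.47	12.14	12.31	9.79	10.25	10.96	9.3	12.2	10.35	11.74	11.29	12.33	12.62	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
LOC110257894	9.71	11.81	12.79	12.41	10.47	10.99	11.43	6.25	7.19	7.26	6.46	6.56	8.01	6.57	9.23	8.65	6.88	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
LOC396706	1.53	1.95	2.21	2.11	1.43	2.3	1.84	1.23	1.41	1.78	2.06	2.13	2.02	2.1	2.06	1.55	1.91	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
LOC100625207	61.73	61	66.52	71.81	55.29	68.56	71.78	52.46	56.2	58.09	51.27	45.83	45.54	50.78	62.94	53.79	58.19	0	0	0	0	0.07	0	0	0	0	0	0.2	0	0	0.08	0	0.16	0.22	0
LOC110255257	15.17	17.72	15.07	17.9	16.46	16.24	17.03	13.16	15.04	13.03	12.85	12.2	13.43	13.2	17.32	12.73	15.37	0	0.07	0	0	0.15	0	0	0	0.07	0	0	0.08	0	0	0	0	0	0
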