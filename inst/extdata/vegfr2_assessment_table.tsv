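# VEGFR2 pharmacophore model assessment (20 representative models screened
# against a 40-active / 1200-decoy test set). Transcribed printed values.
# Note: this table's N column equals TP+FP+FN, and its printed Ya and E
# cells use that N as denominator (see package vignette).
model	n	tp	fp	tn	fn	se	sp	ya	e	acc	dr	f1
VEGFR2_Ph4-6	64	7	24	1176	33	0.18	0.98	0.11	3.39	0.95	0.18	0.2
VEGFR2_Ph4-11	223	28	183	1017	12	0.70	0.85	0.13	3.89	0.84	0.83	0.22
VEGFR2_Ph4-12	63	16	23	1177	24	0.40	0.98	0.25	7.87	0.96	0.41	0.41
VEGFR2_Ph4-17	44	3	4	1196	37	0.08	1.00	0.07	2.11	0.97	0.08	0.13
VEGFR2_Ph4-19	251	30	211	989	10	0.75	0.82	0.12	3.71	0.82	0.91	0.21
VEGFR2_Ph4-21	41	0	1	1199	40	0.00	1.00	0.00	0.00	0.97	0.00	0.00
VEGFR2_Ph4-86	66	3	26	1174	37	0.08	0.98	0.05	1.41	0.95	0.08	0.09
VEGFR2_Ph4-92	44	2	4	1196	38	0.05	1.00	0.05	1.41	0.97	0.05	0.09
VEGFR2_Ph4-95	1164	39	1124	76	1	0.98	0.06	0.03	1.04	0.09	15.39	0.06
VEGFR2_Ph4-99	140	38	100	1100	2	0.95	0.92	0.27	8.41	0.92	1.04	0.43
VEGFR2_Ph4-100	116	38	76	1124	2	0.95	0.94	0.33	10.16	0.94	1.01	0.49
VEGFR2_Ph4-101	123	39	83	1117	1	0.98	0.93	0.32	9.83	0.93	1.05	0.48
VEGFR2_Ph4-102	134	38	94	1106	2	0.95	0.92	0.28	8.79	0.92	1.03	0.44
VEGFR2_Ph4-103	113	38	73	1127	2	0.95	0.94	0.34	10.42	0.94	1.01	0.50
VEGFR2_Ph4-104	109	38	69	1131	2	0.95	0.94	0.35	10.81	0.94	1.01	0.52
VEGFR2_Ph4-105	264	39	224	976	1	0.98	0.81	0.15	4.58	0.82	1.2	0.26
VEGFR2_Ph4-106	225	38	185	1015	2	0.95	0.85	0.17	5.24	0.85	1.12	0.29
VEGFR2_Ph4-107	201	38	161	1039	2	0.95	0.87	0.19	5.86	0.87	1.1	0.32
VEGFR2_Ph4-108	162	38	122	1078	2	0.95	0.90	0.23	7.27	0.9	1.06	0.38
VEGFR2_Ph4-109	122	38	82	1118	2	0.95	0.93	0.31	9.66	0.93	1.02	0.48
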