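# FAK pharmacophore model assessment (14 models screened against a
# 17-active / 983-decoy test set). Transcribed printed values.
# N = TP+FP; Ya and E use the standard hits denominator.
model	n	tp	fp	tn	fn	se	sp	ya	e	acc	dr	f1
FAK_Ph4-1	64	15	49	934	2	0.88	0.95	0.23	13.79	0.95	0.93	0.37
FAK_Ph4-2	549	17	532	451	0	1.00	0.46	0.03	1.82	0.47	2.18	0.06
FAK_Ph4-3	42	13	29	954	4	0.76	0.97	0.31	18.21	0.97	0.79	0.44
FAK_Ph4-4	24	12	12	971	5	0.71	0.99	0.50	29.41	0.98	0.71	0.59
FAK_Ph4-5	35	13	22	961	4	0.76	0.98	0.37	21.85	0.97	0.78	0.50
FAK_Ph4-6	204	16	188	795	1	0.94	0.81	0.08	4.61	0.81	1.16	0.14
FAK_Ph4-7	42	13	29	954	4	0.76	0.97	0.31	18.21	0.97	0.79	0.44
FAK_Ph4-8	23	11	12	971	6	0.65	0.99	0.48	28.13	0.98	0.66	0.55
FAK_Ph4-9	26	14	12	971	3	0.82	0.99	0.54	31.67	0.99	0.83	0.65
FAK_Ph4-10	26	14	12	971	3	0.82	0.99	0.54	31.67	0.99	0.83	0.65
FAK_Ph4-11	45	12	33	950	5	0.71	0.97	0.27	15.69	0.96	0.73	0.39
FAK_Ph4-12	32	15	17	966	2	0.88	0.98	0.47	27.57	0.98	0.90	0.61
FAK_Ph4-13	191	15	176	807	2	0.88	0.82	0.08	4.62	0.82	1.07	0.14
FAK_Ph4-14	55	15	40	943	2	0.88	0.96	0.27	16.04	0.96	0.92	0.42
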