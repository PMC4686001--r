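condition_id	intended_class	n_replicates	n_true_sites	site_width_min	site_width_max	sensitivity	site_overlap	false_peak_rate	boundary_jitter	enrichment_fold	library_size	seed
sim01	similar	2	800	150	400	0.92,0.92	1	2	20	5	1e+06	101
sim02	similar	2	900	150	400	0.92,0.92	1	2	20	5	1e+06	102
sim03	similar	2	1000	150	400	0.92,0.92	1	2	20	5	1e+06	103
sim04	similar	2	1100	150	400	0.92,0.92	1	2	20	5	1e+06	104
sim05	similar	2	1200	150	400	0.92,0.92	1	2	20	5	1e+06	105
sim06	similar	2	800	150	400	0.92,0.92	1	2	20	5	1e+06	106
sim07	similar	2	900	150	400	0.92,0.92	1	2	20	5	1e+06	107
sim08	similar	2	1000	150	400	0.92,0.92	1	2	20	5	1e+06	108
sim09	similar	2	1100	150	400	0.92,0.92	1	2	20	5	1e+06	109
sim10	similar	2	1200	150	400	0.92,0.92	1	2	20	5	1e+06	110
sim11	similar	2	800	150	400	0.92,0.92	1	2	20	5	1e+06	111
sim12	similar	2	900	150	400	0.92,0.92	1	2	20	5	1e+06	112
sim13	similar	2	1000	150	400	0.92,0.92	1	2	20	5	1e+06	113
sim14	similar	2	1100	150	400	0.92,0.92	1	2	20	5	1e+06	114
sim15	similar	2	1200	150	400	0.92,0.92	1	2	20	5	1e+06	115
sim16	similar	2	800	150	400	0.92,0.92	1	2	20	5	1e+06	116
sim17	similar	3	900	150	400	0.92,0.92,0.92	1	2	20	5	1e+06	117
sim18	similar	3	1000	150	400	0.92,0.92,0.92	1	2	20	5	1e+06	118
sim19	similar	3	1100	150	400	0.92,0.92,0.92	1	2	20	5	1e+06	119
sim20	similar	3	1200	150	400	0.92,0.92,0.92	1	2	20	5	1e+06	120
sen01	sensitive	2	800	150	400	0.95,0.30	1	2	20	5	1e+06	201
sen02	sensitive	2	900	150	400	0.95,0.30	1	2	20	5	1e+06	202
sen03	sensitive	2	1000	150	400	0.95,0.30	1	2	20	5	1e+06	203
sen04	sensitive	2	1100	150	400	0.95,0.30	1	2	20	5	1e+06	204
sen05	sensitive	2	1200	150	400	0.95,0.30	1	2	20	5	1e+06	205
sen06	sensitive	2	800	150	400	0.95,0.30	1	2	20	5	1e+06	206
sen07	sensitive	2	900	150	400	0.95,0.30	1	2	20	5	1e+06	207
sen08	sensitive	2	1000	150	400	0.95,0.30	1	2	20	5	1e+06	208
sen09	sensitive	2	1100	150	400	0.95,0.30	1	2	20	5	1e+06	209
sen10	sensitive	2	1200	150	400	0.95,0.30	1	2	20	5	1e+06	210
sen11	sensitive	2	800	150	400	0.95,0.30	1	2	20	5	1e+06	211
sen12	sensitive	2	900	150	400	0.95,0.30	1	2	20	5	1e+06	212
sen13	sensitive	2	1000	150	400	0.95,0.30	1	2	20	5	1e+06	213
sen14	sensitive	2	1100	150	400	0.95,0.30	1	2	20	5	1e+06	214
sen15	sensitive	2	1200	150	400	0.95,0.30	1	2	20	5	1e+06	215
sen16	sensitive	2	800	150	400	0.95,0.30	1	2	20	5	1e+06	216
sen17	sensitive	2	900	150	400	0.95,0.30	1	2	20	5	1e+06	217
sen18	sensitive	2	1000	150	400	0.95,0.30	1	2	20	5	1e+06	218
sen19	sensitive	2	1100	150	400	0.95,0.30	1	2	20	5	1e+06	219
sen20	sensitive	2	1200	150	400	0.95,0.30	1	2	20	5	1e+06	220
dis01	dissimilar	2	800	150	400	0.90,0.90	0.2	2	20	5	1e+06	301
dis02	dissimilar	2	900	150	400	0.90,0.90	0.2	2	20	5	1e+06	302
dis03	dissimilar	2	1000	150	400	0.90,0.90	0.2	2	20	5	1e+06	303
dis04	dissimilar	2	1100	150	400	0.90,0.90	0.2	2	20	5	1e+06	304
dis05	dissimilar	2	1200	150	400	0.90,0.90	0.2	2	20	5	1e+06	305
dis06	dissimilar	2	800	150	400	0.90,0.90	0.2	2	20	5	1e+06	306
dis07	dissimilar	2	900	150	400	0.90,0.90	0.2	2	20	5	1e+06	307
dis08	dissimilar	2	1000	150	400	0.90,0.90	0.2	2	20	5	1e+06	308
dis09	dissimilar	2	1100	150	400	0.90,0.90	0.2	2	20	5	1e+06	309
dis10	dissimilar	2	1200	150	400	0.90,0.90	0.2	2	20	5	1e+06	310
dis11	dissimilar	2	800	150	400	0.90,0.90	0.2	2	20	5	1e+06	311
dis12	dissimilar	2	900	150	400	0.90,0.90	0.2	2	20	5	1e+06	312
dis13	dissimilar	2	1000	150	400	0.90,0.90	0.2	2	20	5	1e+06	313
dis14	dissimilar	2	1100	150	400	0.90,0.90	0.2	2	20	5	1e+06	314
dis15	dissimilar	2	1200	150	400	0.90,0.90	0.2	2	20	5	1e+06	315
dis16	dissimilar	2	800	150	400	0.90,0.90	0.2	2	20	5	1e+06	316
dis17	dissimilar	3	900	150	400	0.90,0.90,0.90	0.2	2	20	5	1e+06	317
dis18	dissimilar	3	1000	150	400	0.90,0.90,0.90	0.2	2	20	5	1e+06	318
dis19	dissimilar	3	1100	150	400	0.90,0.90,0.90	0.2	2	20	5	1e+06	319
dis20	dissimilar	3	1200	150	400	0.90,0.90,0.90	0.2	2	20	5	1e+06	320
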