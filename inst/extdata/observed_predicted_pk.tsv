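# Observed and model-predicted pharmacokinetic parameters of cefepime after IV
# infusion, transcribed as printed from the published comparison tables
# (healthy, pediatric, moderate/severe renal impairment, obese).
# parameter units: auc_0_inf ug/mL*h; cmax ug/mL; cl L/h (pediatric cl L/h/kg).
# printed_ratio is the table's own (sometimes truncated) display value.
# anomaly = 1 flags the healthy 1000 mg Cmax block that duplicates the CL
# values in the source table; rows are preserved as printed.
# ratio_mismatch = 1 flags the two cells whose printed ratio differs from the
# recomputed observed/predicted quotient by more than one unit in the last
# printed digit (healthy 500 mg cmax: 32.0/30.6 = 1.05 but printed 1.06;
# obese auc_0_inf: 244.69/220.39 = 1.11 but printed 1.10).
population	parameter	dose_mg	observed	predicted	printed_ratio	anomaly	ratio_mismatch	study
healthy	auc_0_inf	2000	253.2	224.0	1.13	0	0	s155
healthy	auc_0_inf	2000	250.0	218.8	1.14	0	0	s045
healthy	auc_0_inf	2000	271.3	203.4	1.33	0	0	s035
healthy	auc_0_inf	2000	221.5	236.1	0.93	0	0	s105
healthy	auc_0_inf	2000	264.7	236.1	1.12	0	0	s105
healthy	auc_0_inf	2000	219.6	236.0	0.93	0	0	s105
healthy	auc_0_inf	2000	248.0	236.1	1.05	0	0	s105
healthy	auc_0_inf	1000	140.2	109.6	1.27	0	0	s035
healthy	auc_0_inf	1000	150.6	123.0	1.22	0	0	s045
healthy	auc_0_inf	1000	147.0	103.6	1.41	0	0	s035
healthy	auc_0_inf	1000	128.6	113.6	1.13	0	0	s025
healthy	auc_0_inf	1000	173.8	123.0	1.41	0	0	s045
healthy	auc_0_inf	500	58.6	54.1	1.08	0	0	s045
healthy	auc_0_inf	500	66.5	51.8	1.28	0	0	s035
healthy	auc_0_inf	250	34.5	27.3	1.26	0	0	s045
healthy	auc_0_inf	250	36.4	25.9	1.40	0	0	s035
healthy	auc_0_inf	125	17.9	13.0	1.37	0	0	s035
healthy	auc_0_inf	62.5	7.3	6.3	1.15	0	0	s035
healthy	cmax	2000	126.3	111.3	1.13	0	0	s155
healthy	cmax	2000	118.1	122.3	0.96	0	0	s045
healthy	cmax	2000	129.4	85.2	1.51	0	0	s035
healthy	cmax	2000	150.6	161.8	0.93	0	0	s105
healthy	cmax	2000	173.1	158.6	1.09	0	0	s105
healthy	cmax	2000	99.1	154.7	0.64	0	0	s105
healthy	cmax	2000	128.4	145.0	0.88	0	0	s105
healthy	cmax	1000	7.1	9.1	0.78	1	0	s035
healthy	cmax	1000	6.6	8.1	0.81	1	0	s045
healthy	cmax	1000	6.8	9.6	0.70	1	0	s035
healthy	cmax	1000	7.8	8.8	0.88	1	0	s025
healthy	cmax	1000	5.8	8.1	0.71	1	0	s045
healthy	cmax	500	32.0	30.6	1.06	0	1	s045
healthy	cmax	500	31.7	22.4	1.41	0	0	s035
healthy	cmax	250	16.8	15.3	1.09	0	0	s045
healthy	cmax	250	15.8	11.2	1.41	0	0	s035
healthy	cmax	125	9.3	5.6	1.66	0	0	s035
healthy	cmax	62.5	3.5	3.0	1.16	0	0	s035
healthy	cl	2000	7.9	8.9	0.88	0	0	s155
healthy	cl	2000	8.0	9.1	0.87	0	0	s045
healthy	cl	2000	7.4	9.8	0.75	0	0	s035
healthy	cl	2000	9.0	8.5	1.05	0	0	s105
healthy	cl	2000	8.1	8.5	0.95	0	0	s105
healthy	cl	2000	9.1	8.5	1.07	0	0	s105
healthy	cl	2000	7.6	8.5	0.89	0	0	s105
healthy	cl	1000	7.1	9.1	0.78	0	0	s035
healthy	cl	1000	6.6	8.1	0.81	0	0	s045
healthy	cl	1000	6.8	9.6	0.70	0	0	s035
healthy	cl	1000	7.8	8.8	0.88	0	0	s025
healthy	cl	1000	5.8	8.1	0.71	0	0	s045
healthy	cl	500	8.5	9.2	0.92	0	0	s045
healthy	cl	500	7.5	9.6	0.78	0	0	s035
healthy	cl	250	7.2	9.1	0.79	0	0	s045
healthy	cl	250	6.9	9.6	0.71	0	0	s035
healthy	cl	125	7.0	9.6	0.72	0	0	s035
healthy	cl	62.5	8.6	9.9	0.86	0	0	s035
pediatric	cl	NA	0.18	0.20	0.9	0	0	s180
pediatric	cmax	NA	164.45	182.78	0.89	0	0	s180
pediatric	auc_0_inf	NA	259.49	255.56	1.01	0	0	s180
severe_ckd	cmax	1000	62.55	68.14	0.91	0	0	s035
severe_ckd	cl	1000	1.46	2.4	0.6	0	0	s035
severe_ckd	auc_0_inf	1000	684.56	415.32	1.64	0	0	s035
moderate_ckd	cmax	1000	69.1	67.3	1.02	0	0	s035
moderate_ckd	cl	1000	3.44	6.57	0.52	0	0	s035
moderate_ckd	auc_0_inf	1000	290.109	152.14	1.9	0	0	s035
obese	cl	2000	8.21	9.16	0.89	0	0	s190
obese	cmax	2000	75.98	94.80	0.80	0	0	s190
obese	auc_0_inf	2000	244.69	220.39	1.10	0	1	s190
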