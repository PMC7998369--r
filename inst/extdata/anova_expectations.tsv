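source	band	effect	F	eta2p	B01	B10	pH0	pH1	mark
resting_power	theta	ENV	1.79	0.08	1.86	0.54	0.65	0.35	†
resting_power	theta	RS	10.38	0.34	0.06	17.60	0.05	0.95	†††
resting_power	theta	ELEC	28.52	0.59	0.00	2400.18	0.00	1.00	†††
resting_power	theta	ENV × RS	0.09	0.01	4.36	0.23	0.81	0.19	††
resting_power	theta	ENV × ELEC	0.02	0.00	4.53	0.22	0.82	0.18	††
resting_power	theta	RS × ELEC	0.00	0.00	4.58	0.22	0.82	0.18	††
resting_power	theta	ENV × RS × ELEC	0.60	0.03	3.37	0.30	0.77	0.23	††
resting_power	alpha	ENV	0.25	0.01	4.03	0.25	0.80	0.20	††
resting_power	alpha	RS	29.35	0.60	0.00	2866.86	0.00	1.00	†††
resting_power	alpha	ELEC	9.43	0.32	0.08	12.59	0.07	0.93	†††
resting_power	alpha	ENV × RS	0.00	0.00	4.58	0.22	0.82	0.18	††
resting_power	alpha	ENV × ELEC	0.39	0.02	3.74	0.27	0.79	0.21	††
resting_power	alpha	RS × ELEC	3.84	0.16	0.72	1.38	0.42	0.58	†
resting_power	alpha	ENV × RS × ELEC	0.06	0.00	4.45	0.22	0.82	0.18	††
resting_power	beta	ENV	4.74	0.19	0.49	2.04	0.33	0.67	†
resting_power	beta	RS	5.32	0.21	0.38	2.60	0.28	0.72	†
resting_power	beta	ELEC	8.17	0.29	0.13	7.97	0.11	0.89	††
resting_power	beta	ENV × RS	0.38	0.02	3.77	0.27	0.79	0.21	††
resting_power	beta	ENV × ELEC	0.22	0.01	4.08	0.25	0.80	0.20	††
resting_power	beta	RS × ELEC	1.25	0.06	2.43	0.41	0.71	0.29	†
resting_power	beta	ENV × RS × ELEC	0.52	0.03	3.50	0.29	0.78	0.22	††
pasat_power	theta	ENV	0.61	0.03	3.34	0.30	0.77	0.23	††
pasat_power	theta	TASK	1.11	0.05	2.60	0.38	0.72	0.28	†
pasat_power	theta	ELEC	59.17	0.75	0.00	410005.21	0.00	1.00	†††
pasat_power	theta	ENV × TASK	3.32	0.14	0.92	1.09	0.48	0.52	†
pasat_power	theta	ENV × ELEC	0.05	0.00	4.48	0.22	0.82	0.18	††
pasat_power	theta	TASK × ELEC	0.02	0.00	4.54	0.22	0.82	0.18	††
pasat_power	theta	ENV × TASK × ELEC	0.05	0.00	4.45	0.22	0.82	0.18	††
pasat_power	alpha	ENV	0.18	0.01	4.17	0.24	0.81	0.19	††
pasat_power	alpha	TASK	14.07	0.41	0.02	58.68	0.02	0.98	†††
pasat_power	alpha	ELEC	11.29	0.36	0.04	23.94	0.04	0.96	†††
pasat_power	alpha	ENV × TASK	0.03	0.00	4.50	0.22	0.82	0.18	††
pasat_power	alpha	ENV × ELEC	0.02	0.00	4.54	0.22	0.82	0.18	††
pasat_power	alpha	TASK × ELEC	1.68	0.08	1.96	0.51	0.66	0.34	†
pasat_power	alpha	ENV × TASK × ELEC	0.34	0.02	3.84	0.26	0.79	0.21	††
pasat_power	beta	ENV	0.66	0.03	3.25	0.31	0.76	0.24	††
pasat_power	beta	TASK	1.02	0.05	2.72	0.37	0.73	0.27	†
pasat_power	beta	ELEC	29.10	0.59	0.00	2720.88	0.00	1.00	NA
pasat_power	beta	ENV × TASK	1.31	0.06	2.36	0.42	0.70	0.30	†
pasat_power	beta	ENV × ELEC	0.03	0.00	4.52	0.22	0.82	0.18	††
pasat_power	beta	TASK × ELEC	7.01	0.26	0.20	5.12	0.16	0.84	NA
pasat_power	beta	ENV × TASK × ELEC	0.89	0.04	2.90	0.35	0.74	0.26	†
variability	rest_theta	ENV	2.09	0.10	1.61	0.62	0.62	0.38	†
variability	rest_theta	RS	10.32	0.34	0.06	17.22	0.05	0.95	†††
variability	rest_theta	ENV × RS	0.39	0.02	3.74	0.27	0.79	0.21	††
variability	rest_alpha	ENV	0.44	0.02	3.65	0.27	0.79	0.21	††
variability	rest_alpha	RS	30.72	0.61	0.00	3823.47	0.00	1.00	†††
variability	rest_alpha	ENV × RS	0.04	0.00	4.49	0.22	0.82	0.18	††
variability	rest_beta	ENV	4.37	0.18	0.57	1.74	0.36	0.64	†
variability	rest_beta	RS	6.20	0.24	0.27	3.71	0.21	0.79	††
variability	rest_beta	ENV × RS	0.10	0.01	4.34	0.23	0.81	0.19	††
variability	pasat_theta	ENV	1.24	0.06	2.44	0.41	0.71	0.29	†
variability	pasat_theta	TASK	3.36	0.14	0.90	1.12	0.47	0.53	†
variability	pasat_theta	ENV × TASK	4.21	0.17	0.62	1.62	0.38	0.62	†
variability	pasat_alpha	ENV	0.38	0.02	3.76	0.27	0.79	0.21	††
variability	pasat_alpha	TASK	20.82	0.51	0.00	390.76	0.00	1.00	†††
variability	pasat_alpha	ENV × TASK	0.25	0.01	4.03	0.25	0.80	0.20	††
variability	pasat_beta	ENV	0.61	0.03	3.34	0.30	0.77	0.23	††
variability	pasat_beta	TASK	0.43	0.02	3.67	0.27	0.79	0.21	††
variability	pasat_beta	ENV × TASK	2.31	0.10	1.45	0.69	0.59	0.41	†
text	beta	PASAT posterior-frontal decomposition	24.32	NA	NA	927.41	0.00	1.00	NA
text	beta	eyes-open posterior-frontal decomposition	4.96	NA	NA	2.23	0.31	0.69	NA
text	scores	PASAT score environment	1.22	NA	2.47	NA	0.71	0.29	NA
text	corr	weather correlations ceiling	NA	NA	4.47	NA	0.82	0.18	NA
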