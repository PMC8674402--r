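qtl	donors	chr	interval_start	interval_end	length_cm	a_mean	a_sd	r2_mean	r2_sd	members
qLTG1	W14	1	123.1	139.8	16.7	-0.17	0.01	29.0	0.6	S1,S2
qLTG2	W08,W09	2	102.7	132.9	30.2	0.11	0.01	19.5	0.8	S3,S4
qLTG3a	W06	3	22.7	29.3	6.6	0.17	0.01	33.0	3.2	S5,S6,S7
qLTG3b	W17	3	108.6	125.0	16.4	-0.10	0.01	19.2	5.8	S8
qLTG4	W06	4	67.7	80.6	12.9	-0.16	0.03	28.5	3.8	S9,S10,S11
qLTG5	W01,W11	5	113.9	116.5	2.6	0.14	0.01	28.4	0.5	S12,S13
qLTG6	W23,W27	6	0.7	17.3	16.6	0.10	0.07	19.5	15.0	S14,S15
qLTG7a	W06	7	18.5	28.5	10.0	-0.22	0.09	39.4	3.7	S16
qLTG7b	W05	7	55.8	80.4	24.6	-0.24	0.08	39.9	8.9	S17
qLTG8a	W06	8	36.5	43.0	6.5	0.15	0.02	26.9	4.4	S18
qLTG8b	W06	8	82.6	91.7	9.1	0.16	0.01	31.0	3.7	S19,S20
qLTG9	W27	9	48.0	65.1	17.1	-0.21	0.01	34.2	6.0	S21
qLTG11a	W06	11	39.8	59.3	19.5	0.15	0.01	31.3	1.3	S22,S23
qLTG11b	W17	11	81.9	97.3	15.4	-0.19	0.07	34.1	9.7	S24
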