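line_id	donor	chr	core_start_marker	core_end_marker	max_start_marker	max_end_marker	detected
S1	W14	1	RM297	RM212	RM246	RM315	TRUE
S2	W14	1	RM237	RM212	RM5	RM315	TRUE
S3	W09	2	RM263	RM530	RM106	RM240	TRUE
S4	W08	2	RM263	RM166	PSM122	RM213	TRUE
S5	W06	3	RM489	PSM428	RM175	PSM429	TRUE
S6	W06	3	RM489	RM218	RM231	RM563	TRUE
S7	W06	3	RM545	RM218	RM489	RM563	TRUE
S8	W17	3	RM426	RM168	PSM127	RM186	TRUE
S9	W06	4	RM273	RM252	RM119	RM241	TRUE
S10	W06	4	RM273	RM252	PSM194	RM241	TRUE
S11	W06	4	PSM196	RM252	PSM358	RM241	TRUE
S12	W11	5	RM31	PSM386	RM480	End	TRUE
S13	W01	5	RM178	RM334	PSM384	End	TRUE
S14	W27	6	RM508	RM217	End	RM253	TRUE
S15	W23	6	RM508	RM121	End	RM136	TRUE
S16	W06	7	RM481	PSM142	RM481	PSM143	TRUE
S17	W05	7	RM2	RM10	PSM142	PSM353	TRUE
S18	W06	8	PSM155	RM547	PSM155	PSM393	TRUE
S19	W06	8	RM556	RM210	RM284	RM80	TRUE
S20	W06	8	RM515	OSR7	PSM394	RM447	TRUE
S21	W27	9	RM434	RM410	RM105	RM257	TRUE
S22	W06	11	PSM409	PSM412	PSM409	PSM414	TRUE
S23	W06	11	PSM175	RM536	PSM174	PSM415	TRUE
S24	W17	11	PSM365	PSM417	RM21	PSM460	TRUE
S25	W06	3	X25B	X25C	X25A	X25D	FALSE
S26	W06	3	X26B	X26C	X26A	X26D	FALSE
S27	W01	5	RM31	End	X27A	End	FALSE
S28	W05	7	X28B	X28C	X28A	X28D	FALSE
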