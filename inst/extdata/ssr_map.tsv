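marker	chr	cm
RM5	1	103.0
RM237	1	105.6
RM246	1	120.0
RM297	1	123.1
RM212	1	139.8
RM315	1	142.0
PSM122	2	98.0
RM106	2	100.0
RM263	2	102.7
RM530	2	132.9
RM240	2	135.0
RM166	2	157.2
RM213	2	160.0
X25A	3	8.0
RM231	3	10.0
X25B	3	10.0
RM175	3	12.0
RM489	3	20.0
X25C	3	22.7
X25D	3	24.0
RM545	3	26.8
X26A	3	28.0
X26B	3	29.3
PSM428	3	36.1
PSM429	3	40.0
X26C	3	45.0
X26D	3	46.0
RM218	3	48.7
RM563	3	55.0
PSM127	3	105.0
RM426	3	108.6
RM168	3	125.0
RM186	3	130.0
PSM358	4	30.0
PSM196	4	33.6
PSM194	4	62.0
RM119	4	65.0
RM273	4	67.7
RM252	4	80.6
RM241	4	83.0
PSM384	5	100.0
RM178	5	103.0
X27A	5	112.0
RM480	5	113.9
RM31	5	116.5
PSM386	5	124.9
RM334	5	125.4
RM508	6	0.7
RM217	6	17.3
RM253	6	20.0
RM121	6	45.6
RM136	6	50.0
RM481	7	18.5
X28A	7	27.0
X28B	7	27.5
PSM142	7	28.5
PSM143	7	28.5
RM2	7	35.0
X28C	7	55.8
X28D	7	57.0
RM10	7	80.4
PSM353	7	82.0
PSM155	8	36.5
RM547	8	41.0
PSM393	8	43.0
RM284	8	80.0
PSM394	8	81.0
RM556	8	82.6
RM515	8	83.0
RM210	8	91.7
RM80	8	94.0
OSR7	8	119.4
RM447	8	121.0
RM105	9	46.0
RM434	9	48.0
RM410	9	65.1
RM257	9	67.0
PSM409	11	30.5
PSM174	11	37.0
PSM175	11	39.8
PSM412	11	59.3
PSM414	11	61.0
RM536	11	80.0
RM21	11	80.5
PSM415	11	81.0
PSM365	11	81.9
PSM417	11	97.3
PSM460	11	99.0
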