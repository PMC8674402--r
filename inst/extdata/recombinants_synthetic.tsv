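recomb_id	chrom	het_start_bp	het_end_bp	marker_id	r	p
S6_R1	3	6026000	6500000	P8	0.70	0.0001
S6_R2	3	5700000	6026000	P1	0.10	0.40
S6_R3	3	5800000	6358700	P8	0.56	0.0005
S6_R4	3	6358700	6900000	P13	0.08	0.52
S6_R5	3	6500000	7100000	P13	0.05	0.67
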