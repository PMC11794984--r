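factor	contrast	statistic	a	b	c	d
fusion_high	ML_vs_MR	fisher	11	0	0	20
fusion_weak	MR2_vs_MR1	fisher	7	5	0	8
ptch1_mut	MR_vs_ML	fisher	9	11	0	11
pax7_lineage	MR_vs_ML	fisher	9	11	0	11
myf6_lineage	ML_vs_MR	fisher	7	4	4	16
pax3_lineage	ML_vs_MR	fisher	3	8	3	17
myf5_lineage	ML_vs_MR	fisher	1	10	4	16
rb1_mut	ML_vs_MR	fisher	3	8	2	18
pax7_lineage	MR2_vs_MR1	fisher	9	3	0	8
myf5_lineage	MR1_vs_MR2	fisher	4	4	0	12
rb1_mut	MR1_vs_MR2	fisher	0	8	2	10
myf6_x_fusion_high	agreement	kappa	7	4	4	16
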