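sample	model	genotype
28402	Pax3	MCre(Cre/WT) Ptch1(F1-2m) Trp53(F2-10/F2-10)
22520	Pax3	MCre(Cre/WT) Ptch1(F1-2m) Trp53(F2-10/F2-10)
20745	Pax3	MCre(Cre/WT) Ptch1(F1-2m) Trp53(F2-10/F2-10)
24107	Pax3-P3F	MCre(Cre/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10)
23969	Pax3-P3F	MCre(Cre/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10)
24988	Pax3-P3F	MCre(Cre/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10)
24085	Myf5	Myf5(ICNm/WT) Ptch1(F1-2m/WT) Trp53(F2-10/DEL2-10)
24055	Myf5	Myf5(ICNm/WT) Ptch1(F1-2m/WT) Trp53(F2-10/F2-10)
20938	Myf5	Myf5(ICNm/WT) Ptch1(F1-2m/WT) Trp53(F2-10/F2-10)
23478	Myf5	Myf5(ICNm/WT) Ptch1(F1-2m/WT) Trp53(F2-10/F2-10) ROSA26(LUSAP)
24014	Myf5-P3F	Myf5(ICNm/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10)
32577	Myf6	Myf6(ICNm/WT) Trp53(F2-10/F2-10)
37125	Myf6	Myf6(ICNm/WT) Trp53(F2-10/F2-10) Rosa26(LUSAP/Any) Ptch1(WT/WT)
21353	Myf6	Myf6(ICNm/WT) Trp53(F2-10/F2-10) Rosa26(LUSeAP/WT)
35029	Myf6	Myf6(ICNm/WT) Trp53(F2-10/F2-10) Rb1(Flox/Flox)
32945	Myf6-P3F	Myf6(ICNm/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10)
26404	Myf6-P3F	Myf6(ICNm/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10)
44927	Myf6-P3F	Myf6(ICNm/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Hairless(Skh1/WT)
38917	Myf6-P3F	Myf6(ICNm/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Rb1(Flox/Flox)
38172	Myf6-P3F	Myf6(ICNm/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Rb1(Flox/Flox) Rosa26(LUSAP/Any)
66788	Myf6-P3F	Myf6(ICNm/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Rosa26(LUSAPp/Any) Hairless(Skh1/Skh1)
45065	Myf6-P3F	Myf6(ICNm/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Rb1(Flox/Flox) Rosa26(LUSAP/WT)
33940	Pax7	ROSA26(Yello/LUSAP) Trp53(F2-10/F2-10) Pax7(CreERp/WT)
34605	Pax7	ROSA26(WT/WT) Ptch1(F1-2m/WT) Trp53(F2-10/F2-10) Pax7(CreERp/WT)
31431	Pax7-P3F	Pax7(CreERp/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Rosa26(LUSAP/Any)
28285	Pax7-P3F	Pax7(CreERp/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Rosa26(LUSAPm/WT)
29418	Pax7-P3F	Pax7(CreERp/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Rosa26(LUSAPm/WT) ZRED-Tg(Bgeo/WT)
35512	Pax7-P3F	Pax7(CreERp/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Rb1(Flox/Flox)
31430	Pax7-P3F	Pax7(CreERp/WT) Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Rosa26(Lusap/WT)
26568	Pax7-P3F	Pax3(P3Fm/P3Fm) ROSA26(WT/WT) Trp53(F2-10/F2-10) Pax7(CreERp/WT)
29138	Pax7-P3F	Pax3(P3Fm/P3Fm) Trp53(F2-10/F2-10) Pax7(CreERp/WT)
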