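sample	main	subset
28402	MR	MR1
22520	MR	MR2
20745	MR	MR2
24107	ML	
23969	ML	
24988	ML	
24085	MR	MR1
24055	MR	MR1
20938	MR	MR1
23478	MR	MR1
24014	ML	
32577	MR	MR1
37125	MR	MR1
21353	MR	MR1
35029	MR	MR2
32945	ML	
26404	ML	
44927	ML	
38917	ML	
38172	ML	
66788	ML	
45065	ML	
33940	MR	MR2
34605	MR	MR2
31431	MR	MR2
28285	MR	MR2
29418	MR	MR2
35512	MR	MR2
31430	MR	MR2
26568	MR	MR2
29138	MR	MR2
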