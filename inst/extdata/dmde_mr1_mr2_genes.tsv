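gene_symbol	region	methyl	expres	patel	wei	danielli
ABLIM2	body	hypo	over	Myoc
ABLIM3	body	hypo	over	Myoc
ACTC1	prom	hypo	over	Myoc	Mus	MuSC,Cycl,Diff
CACNA1S	prom	hypo	over	Myoc
CACNA2D3	body	hypo	over	Myob
CAV3	prom	hypo	over	Myoc
CCND3	prom	hypo	over			MuSC
CCND3	body	hypo	over			MuSC
COL15A1	prom	hyper	over	Meso	Mese
COL15A1	body	hypo	over	Meso	Mese
COL25A1	body	hyper	over	Myoc	Mus
COL25A1	body	hypo	over	Myoc	Mus
COL4A1	body	hypo	over	Meso	Mese	Diff
CORO1C	prom	hyper	under	Myoc
CORO1C	body	hyper	under	Myoc
DNMT1	body	hypo	under			MuSC
ELN	prom	hyper	over	Meso	Mese
ELN	body	hypo	over	Meso	Mese
ENPP6	prom	hypo	over	Myoc
EPHB3	prom	hypo	over		Fnco
EPHB3	body	hypo	over		Fnco
EPS8	prom	hypo	under	Meso	Mese
EPS8	body	hypo	under	Meso	Mese
FZD4	body	hypo	over		Fnco
FZD7	prom	hypo	over		Fnco
GNAS	prom	hypo	over	Myob
HIP1	body	hyper	over	Myoc
HRC	prom	hypo	over			Diff
ISLR	body	hypo	over			MuSC,Diff
LAMC1	body	hypo	over	Meso	Mese	MuSC
LY6E	body	hyper	under		Fnco
MAST4	body	hypo	under	Meso
MYL1	prom	hypo	over	Myoc	Mus	MuSC,Cycl,Diff
MYL1	body	hypo	over	Myoc	Mus	MuSC,Cycl,Diff
NCALD	prom	hyper	over	Myoc		Diff
NCALD	prom	hypo	over	Myoc		Diff
NCALD	body	hypo	over	Myoc		Diff
NEB	prom	hypo	over	Myoc	Mus	MuSC,Diff
NEB	body	hypo	over	Myoc	Mus	MuSC,Diff
NFIA	body	hypo	over	Myob
PLXNA2	body	hyper	over	Myoc
PLXNA2	body	hypo	over	Myoc
PPP1R14A	body	hypo	over		Mese
PRICKLE1	prom	hypo	over	Meso
PRICKLE1	body	hypo	over	Meso
RYR1	body	hyper	over	Myoc	Mus	Diff
S100A4	prom	hyper	under		Mese	Diff
S100A4	body	hyper	under		Mese	Diff
SMOC1	body	hypo	over	Myoc
SVIL	prom	hypo	over	Myoc
SVIL	body	hyper	over	Myoc
SVIL	body	hypo	over	Myoc
TNFRSF19	body	hypo	over	Myoc
UBE2E3	prom	hypo	under	Myoc		Diff
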