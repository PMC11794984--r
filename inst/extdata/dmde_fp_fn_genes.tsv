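gene_symbol	region	methyl	expres	p3f_target	patel	wei	danielli
ABLIM2	body	hypo	over	FALSE	Myoc
ACAT1	body	hypo	over	FALSE
ACVR1C	body	hyper	over	FALSE
ANKRD50	body	hyper	under	FALSE
BCAT1	body	hypo	under	TRUE	Myoc
BNC2	body	hyper	under	FALSE	Meso
CACNA1C	body	hypo	under	FALSE	Meso
CDH4	body	hyper	over	TRUE	Myob
COL1A2	prom	hyper	under	FALSE	Meso	Mese	MuSC,Diff
CRABP1	body	hypo	under	FALSE
DLL1	body	hypo	over	FALSE
DTNA	body	hypo	under	FALSE	Myoc
EMILIN1	prom	hyper	under	FALSE		Fnco	Diff
EPHA8	body	hyper	over	FALSE
ERRFI1	body	hypo	over	TRUE			MuSC
ESPN	body	hyper	over	FALSE
FGF8	body	hypo	over	TRUE
FMNL2	body	hypo	under	FALSE
GRIP1	prom	hyper	over	TRUE	Myob
HOXC6	body	hyper	under	FALSE		Fnco
HOXD4	prom	hypo	under	FALSE		Fnco
HOXD4	body	hypo	under	FALSE		Fnco
HOXD9	body	hypo	under	FALSE
IGF1	body	hypo	under	FALSE
IRX3	body	hypo	over	FALSE
KCNJ12	body	hypo	over	FALSE
KCNK2	prom	hyper	over	FALSE
KCNK2	body	hypo	over	FALSE
LTBP4	prom	hypo	under	FALSE		Fnco
LTBP4	body	hypo	under	FALSE		Fnco
MAN1C1	body	hypo	over	TRUE
MXRA8	prom	hyper	under	FALSE
NEDD4L	prom	hypo	under	TRUE
OLFML3	body	hyper	under	FALSE
OSBPL3	body	hypo	under	FALSE
RGMA	prom	hyper	under	TRUE
RGMA	body	hyper	under	TRUE
ROR2	body	hypo	under	FALSE	Meso
SCARA5	prom	hypo	over	TRUE
SMAD3	body	hypo	under	FALSE
STK39	body	hypo	under	FALSE
TBX15	body	hypo	over	TRUE
TGFBR2	body	hypo	under	FALSE
ZIC1	prom	hyper	under	TRUE
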