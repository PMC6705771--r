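BCR	bcr
ABL	abl
ABL1	abl1
JAK2	jak2
JAK1	jak1
STAT5	stat5
STAT5B	stat5b
STAT3	stat3
GRB2	grb2
GRB10	grb10
CRKL	crkl
NPM	npm
NPM1	npm1
ALK	alk
ATIC	atic
EWS	ews
EWSR1	ewsr1
FLI1	fli1|fli-1
ERG	erg
TMPRSS2	tmprss2|tmrpss2
EML4	eml4
ETV6	etv6|tel
RUNX1	runx1|aml1
RUNX1T1	runx1t1|eto
PML	pml
RARA	rara|rar
NTRK3	ntrk3
NTRK1	ntrk1
ROS1	ros1
RET	ret
EGFR	egfr
BRAF	braf
KRAS	kras
TP53	tp53
MYC	myc
PTEN	pten
AKT1	akt1
PIK3CA	pik3ca
SRC	src
SOS1	sos1
GAB2	gab2
SHC1	shc1
PDGFRA	pdgfra
PDGFRB	pdgfrb
FGFR1	fgfr1
FGFR3	fgfr3
TACC3	tacc3
CD74	cd74
KIF5B	kif5b
CCND1	ccnd1
MDM2	mdm2
RB1	rb1
SMAD4	smad4
CTNNB1	ctnnb1
NRAS	nras
FLT3	flt3
KMT2A	kmt2a|mll
AFF1	aff1|af4
MAPK1	mapk1
PIK3R1	pik3r1
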