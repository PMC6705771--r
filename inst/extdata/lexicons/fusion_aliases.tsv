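BCR-ABL	BCR-ABL|BCR-ABL1|BCR/ABL|BCR:ABL
EWS-FLI1	EWS-FLI1|EWS-FLI-1|EWSR1-FLI1|EWSR1-FLI-1|EWS-FLI
TMPRSS2-ERG	TMPRSS2-ERG|TMRPSS2-ERG
NPM-ALK	NPM-ALK|NPM1-ALK
ATIC-ALK	ATIC-ALK
BCR-JAK2	BCR-JAK2
EML4-ALK	EML4-ALK
ETV6-RUNX1	ETV6-RUNX1|TEL-AML1
PML-RARA	PML-RARA|PML-RAR
RUNX1-RUNX1T1	RUNX1-RUNX1T1|AML1-ETO
FGFR3-TACC3	FGFR3-TACC3
CD74-ROS1	CD74-ROS1
KIF5B-RET	KIF5B-RET
ETV6-NTRK3	ETV6-NTRK3
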