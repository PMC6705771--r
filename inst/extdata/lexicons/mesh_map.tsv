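leukemia	D007938
chronic myeloid leukemia	D015464
acute lymphoblastic leukemia	D054198
acute myeloid leukemia	D015470
lymphoma	D008223
sarcoma	D012509
prostate cancer	D011471
breast cancer	D001943
lung cancer	D008175
glioblastoma	D005909
cancer	D009369
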