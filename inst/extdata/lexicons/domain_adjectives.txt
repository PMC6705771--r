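small
single
medical
chronic
acute
human
murine
novel
clinical
cellular
molecular
genetic
genomic
oncogenic
tumorigenic
malignant
benign
somatic
germline
recurrent
primary
metastatic
preclinical
therapeutic
pathogenic
constitutive
aberrant
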