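leukemia	leukemia|leukaemia|leukemias
chronic myeloid leukemia	chronic myeloid leukemia|chronic myelogenous leukemia|cml
acute lymphoblastic leukemia	acute lymphoblastic leukemia
acute myeloid leukemia	acute myeloid leukemia|aml
lymphoma	lymphoma|lymphomas|anaplastic large cell lymphoma
sarcoma	sarcoma|sarcomas|ewing sarcoma
prostate cancer	prostate cancer|prostate carcinoma
breast cancer	breast cancer|breast carcinoma
lung cancer	lung cancer|lung carcinoma|lung adenocarcinoma
glioblastoma	glioblastoma|glioblastomas
cancer	cancer|cancers|carcinoma|tumor|tumour|tumors|tumours
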