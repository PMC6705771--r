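# name	pattern	attributes (normalize_* rows: attributes = replacement)
normalize_case	(.+)	\L\1
normalize_separator	[–—/:]	-
fusion_pair	^[A-Za-z0-9]+[-–—/:][A-Za-z0-9]+$	gene_a,gene_b
fusion_chain	^[A-Za-z0-9]+([-–—/:][A-Za-z0-9]+){2,}$	gene_a,gene_b,trailer
fusion_keyword	fusion|fusions|fusion genes|gene fusion|fusion protein|fusion transcripts	keyword
year_range	^(1[89][0-9]{2}|20[0-9]{2})[-–—][0-9]{2,4}$	distractor
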