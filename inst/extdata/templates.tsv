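default	title_pos	Characterization of the {FUSION} {KEYWORD} in {DISEASE}
default	title_neg	A cohort study of biomarker variability in solid tumors
default	opener	We investigated the {FUSION} {KEYWORD} in patients with {DISEASE}.
default	opener	Expression of the {FUSION} {KEYWORD} was confirmed in {DISEASE} samples.
default	opener	The {FUSION} {KEYWORD} was identified by RNA sequencing in {DISEASE}.
default	interaction	{PARTNER} {VERB} the {FUSION} {KEYWORD} in these cells.
default	interaction	Immunoprecipitation showed that {PARTNER} {VERB} {FUSION} {KEYWORD} complexes.
default	coordination	{PARTNER} {VERB} {FUSION} and {FUSION2} in these samples.
default	disease	Notably, {FUSION} causes {DISEASE2} in a subset of patients.
default	filler_pos	These findings were confirmed in independent cell lines.
default	filler_pos	Downstream signaling changes were consistent across replicates.
default	filler_neg	The cohort was assembled at a single center over four years.
default	filler_neg	Baseline characteristics were balanced across study arms.
default	filler_neg	No fusion transcripts were detected in this cohort.
default	distractor	Samples collected from {YEARRANGE} were analyzed in a time-dependent manner.
default	distractor	The cost-effective assay used N-methyl-D-aspartate as a control compound.
default	distractor	A dose-response relationship was observed across age groups.
default	distractor	{GENE} expression levels were measured in all samples.
default	distractor	Patient-derived material from the {YEARRANGE} period was profiled.
default	distractor	The well-tolerated compound showed activity in vitro.
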