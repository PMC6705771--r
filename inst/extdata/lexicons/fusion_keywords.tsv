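fusion	fusion|fusions|fusion protein|fusion proteins|fusion gene|fusion genes|fusion transcript|fusion transcripts|fusion gene transcript|fusion gene transcripts|gene fusion|gene fusions|fusion oncogene|fusion oncoprotein
chimera	chimera|chimeras|chimeric|chimeric protein|chimeric proteins|chimeric gene|chimeric genes|chimeric transcript|chimeric transcripts
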