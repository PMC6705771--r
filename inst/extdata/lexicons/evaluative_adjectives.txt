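effective
potent
selective
specific
significant
important
essential
critical
functional
active
inactive
sensitive
resistant
stable
unstable
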