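pattern	polarity	category	description
\b[A-Z][a-z]+, [A-Z][a-z]+\b	PHI	Name	surname-comma-forename layout
\b[A-Z][a-z]+ [A-Z][a-z]+\b	PHI	Name	forename-surname layout
\b[A-Z][a-z]+ [A-Z]\. [A-Z][a-z]+\b	PHI	Name	forename middle-initial surname layout
\b[A-Z][a-z]+-[A-Z][a-z]+\b	PHI	Name	hyphenated surname layout
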