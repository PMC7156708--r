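pattern	polarity	category	description
(?:\b[A-Z][a-z]+,\s(?:[A-Z]\.\s?)+)|(?:\b(?:[A-Z]\.\s)+[A-Z][a-z]+)|(?:\b[A-Z][a-z]+\s(?:[A-Z]\.\s?)+[A-Z][a-z]+)	PHI	Initials	initials adjacent to a name
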