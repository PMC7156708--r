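pattern	polarity	category	description
(?i)\b[0-9]+(?:\.[0-9]+)?\s?(?:mg|mcg|g|kg|ml|l|mmol|meq|units?|tabs?|tablets?|iu)\b	SAFE	NONE	dosage with unit
(?i)\b[0-9]+(?:\.[0-9]+)?\s?(?:mmhg|bpm|cm|mm|kg/m2)\b	SAFE	NONE	vital sign or measurement with unit
\b[0-9]+(?:\.[0-9]+)?\s?%	SAFE	NONE	percentage
(?i)\b(?:q|bid|tid|qid)\s?[0-9]+h?\b	SAFE	NONE	dosing frequency shorthand
(?i)\b[0-9]+(?:\.[0-9]+)?\s?(?:times|x)\s(?:per|a)\s(?:day|week|month)\b	SAFE	NONE	frequency phrase
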