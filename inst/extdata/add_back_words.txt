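# Common English words re-inserted into the whitelist after name removal.
# These stay in the blacklists (the POS gate handles their proper-noun
# uses) but must remain retrievable as ordinary words.
white
young
price
bell
berry
stone
west
green
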