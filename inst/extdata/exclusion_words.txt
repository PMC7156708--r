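# Starter exclusion list: name tokens that are overwhelmingly common words
# in clinical text and are removed from the built blacklists.
new
walks
knee
home
child
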