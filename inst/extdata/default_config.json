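{
  "obfuscation_char": "*",
  "pos_tagger": "rule",
  "stages": [
    {"name": "safe_regex", "kind": "safe_regex",
     "params": {"library": "extdata:safe_regex.tsv"}},
    {"name": "phi_regex", "kind": "phi_regex",
     "params": {"library": "extdata:phi_regex.tsv"}},
    {"name": "age_rule", "kind": "age_rule",
     "params": {"threshold": 90, "context_radius": 2,
                "trigger_words": ["age", "years old", "y.o."]}},
    {"name": "pos_tag", "kind": "pos_tag", "params": {}},
    {"name": "last_name_blacklist", "kind": "name_blacklist",
     "params": {"last_names": "build:last_names"}},
    {"name": "first_name_blacklist", "kind": "name_blacklist",
     "params": {"first_names": "build:first_names"}},
    {"name": "name_context", "kind": "name_context",
     "params": {"library": "extdata:name_context_regex.tsv"}},
    {"name": "whitelist", "kind": "whitelist",
     "params": {"lexicon": "build:whitelist"}},
    {"name": "initials", "kind": "initials",
     "params": {"library": "extdata:initials_regex.tsv"}}
  ]
}
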