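# phifilter

Rule-based de-identification of free-text clinical notes in R.

Clinical notes are the richest part of the electronic health record, and
the least usable: they contain Protected Health Information (PHI) — names,
dates, phone numbers, record numbers, addresses — whose presence blocks
almost all secondary research use. `phifilter` implements a
privacy-first, configuration-driven cascade that removes PHI from plain
text while preserving the note's exact character layout, together with
the token-level evaluation framework needed to measure how well it does,
and a synthetic annotated-note generator so the whole system can be
developed and tested without touching a single real note.

## The method

A note is tokenized into maximal alphanumeric runs with exact 0-based
character offsets (whitespace and symbols such as `-`, `/`, `#`, `&`,
periods and commas are separators). An ordered stage cascade then labels
tokens under a **first-writer-wins** rule — a stage may move a token from
*unmarked* to *include* (safe) or *exclude* (PHI), and never overwrites an
earlier label, so stage order in the JSON config is priority:

1. **safe patterns** — dosages, lab values, vitals (`50 mg` is not PHI);
2. **PHI patterns** — emails, URLs/IPs, SSNs, phone/fax, dates,
   addresses, record and account numbers, salutation-anchored names;
3. **age rule** — a number adjacent to `age` / `years old` is an age;
   ages ≥ 90 are PHI under HIPAA Safe Harbor, younger ages are safe;
4. **POS tagging** — a deterministic rule tagger (pluggable contract)
   assigns Penn Treebank tags;
5. **name blacklists** — census-style surnames (count ≥ 100) and
   Social-Security-style first names (count ≥ 5 in some birth year
   1879–2017), lowercased; a token in a blacklist is removed only if
   tagged `NNP`, which is what lets "White" survive in "White fluid
   found at…" while being removed in "Patient John White presents…";
6. **name context** — `Jane Doe` / `Doe, Jane` layouts, marked only
   beside an existing blacklist exclusion;
7. **whitelist** — ~medical + common-English vocabulary minus all
   blacklist names (plus curated add-backs); unmarked non-numeric tokens
   found in it become safe, everything else stays unmarked;
8. **initials** — `Doe, J.` / `Jane S. Doe` layouts beside a blacklist
   exclusion.

Final disposition is the safety net: **only tokens marked for inclusion
are retained**. Excluded *and never-labelled* tokens are obfuscated
character-for-character (`John Smith` → `**** *****`), separators are
preserved in place, and any asterisk already present in the input becomes
a space — so output length always equals input length and an output
asterisk always means "removed".

Evaluation is word-level on the character-aligned output: a token is
predicted-PHI iff any of its characters were obfuscated, gold-PHI iff it
intersects a gold span (MAE-style or i2b2-2014-style XML). With
TP/FP/TN/FN counted over tokens,

    Recall    = TP / (TP + FN)      (privacy)
    Precision = TP / (TP + FP)      (information retention)
    F2        = 5·P·R / (4·P + R)   (recall weighted twice)

plus a per-category table of PHI token instances remaining. An i2b2
normalizer re-labels spans Safe Harbor does not cover (isolated years,
seasons, weekdays, lone letters, countries, ages < 90, ≤4-digit surrogate
IDs) from PHI to safe.

## Worked example

```r
library(phifilter)

run_note(note_document("Patient John White presents with pain."))$output_text
#> [1] "Patient **** ***** presents with pain."

run_note(note_document("White fluid found at the wound site."))$output_text
#> [1] "White fluid found at the wound site."

run_note(note_document(
  "Contact jsmith@example.org or 123-45-6789 on 07/14/2012."))$output_text
#> [1] "Contact ******@*******.*** or ***-**-**** on **/**/****."

# synthetic corpus -> default pipeline -> evaluation
synth <- generate_corpus(synth_config(seed = 7, n_notes = 40))
cfg <- default_pipeline_config()
per <- lapply(synth, function(nt)
  evaluate_note(nt$doc, run_note(nt$doc, cfg)$output_text, nt$gold))
corpus_report(per)
#> <metrics_result: 40 notes, 4175 tokens | TP 677 FP 201 TN 3275 FN 22>
#>   recall 96.85%  precision 77.11%  F2 92.13%
```

The first two lines show the POS gate: the same word "White" is removed
as a proper noun and retained as an adjective. The corpus numbers show
the deliberate trade: high recall (missed PHI is a privacy breach) at the
cost of precision (unknown-but-safe words are obfuscated by the safety
net). The leakage table in the report identifies which categories the
false negatives came from.

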