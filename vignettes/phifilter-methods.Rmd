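---
title: "De-identifying clinical notes with phifilter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identifying clinical notes with phifilter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phifilter)
```

## The problem and the model

De-identification must remove every HIPAA identifier from free text in
which *anything* can be a name: the same string can be a surname in one
sentence and a medical term or common word in the next ("White", "MA").
`phifilter` therefore inverts the usual NER framing. Instead of asking
"which words are PHI?", the cascade primarily asks "which words can be
*proven safe*?" and destroys everything it cannot vouch for. The final
disposition rule — only tokens affirmatively marked for inclusion are
retained; excluded **and unlabelled** tokens are obfuscated — is what
makes the whitelist a safety net rather than a convenience: a
never-before-seen token (a misspelled name, a stray identifier) is
removed by default.

Three label states drive the cascade: `UNMARKED` (initial), `INCLUDE`
(proven safe) and `EXCLUDE` (PHI, with a category). Stages obey
first-writer-wins: a label, once set, is never overwritten, so the order
of stages in the JSON configuration is exactly their priority. We apply
this rule globally, including to the whitelist: a token the whitelist
marks safe cannot be re-excluded by the later initials stage. That
choice has a visible consequence discussed under *Known limitations*.

### Stage-by-stage assumptions

* **Tokenization.** Tokens are maximal runs of Unicode letters/digits;
  every other character (whitespace, `-`, `/`, `#`, `&`, periods,
  commas, colons, quotes, apostrophes, and any other symbol) separates.
  Offsets are 0-based half-open, chosen for unambiguous interval
  arithmetic; readers for gold formats convert into this convention.
  Text is NFC-normalised on load. Apostrophes separate by default, so
  "Smith's" tokenizes as `Smith`, `s` — a documented choice, not a claim
  about any other system's behaviour.
* **Pattern stages.** Safe and PHI regular expressions run on the *raw
  text* and are projected onto tokens; a partial character overlap
  claims the whole token (privacy-conservative). Context conditions
  (e.g. a number next to a trigger word) are expressed with lookaround
  on the raw text or in dedicated rules. The shipped libraries cover
  every category the cascade needs — emails, URLs/IPs, SSNs, phone/fax,
  several date formats, addresses and postal codes, record/account
  identifiers, salutation-anchored names — but are curated
  representatives, not a claim of parity with any particular historical
  pattern set.
* **Age rule.** A digit token within 2 tokens of an age trigger
  (`age`, `years old`, `y.o.`) is an age: `>= 90` is PHI (the HIPAA
  Safe Harbor cut), `< 90` is safe. Dosages are already safe by the
  time this rule runs, so `50 mg` is never read as an age.
* **POS gate.** Name blacklists fire only on tokens tagged `NNP`. The
  shipped tagger is deterministic and rule-based (digits → `CD`;
  lexicon lookups; capitalised mid-sentence → `NNP`; capitalised
  sentence-initial words fall back to the lexicon before defaulting to
  `NNP`), so test outcomes never depend on a statistical model version.
  Any tagger honouring the "one Penn-Treebank tag per token" contract
  can be plugged in; a statistical tagger will tag more accurately
  mid-corpus but is also the main source of precision errors
  (capitalised non-names read as proper nouns).
* **Blacklists.** Surnames with count ≥ 100 in a census-style table and
  first names with count ≥ 5 in at least one birth year 1879–2017 in a
  Social-Security-style table, tokenized and lowercased; a curated
  exclusion list removes name tokens that are overwhelmingly common
  words. Detection assigns a generic `Name` category — patient versus
  provider is not decidable from text alone and is an evaluation-side
  mapping.
* **Name context and initials.** Layout patterns (`Jane Doe`,
  `Doe, Jane`, `Jane S. Doe`, hyphenated; `Doe, J.`) mark tokens only
  when an adjacent token (stream distance 1) was excluded by a
  blacklist. "Adjacent" is the minimal reading of the contextual
  condition; the radius is configurable. Name-context candidates are
  additionally required to be proper nouns when tags are available,
  otherwise a pattern like `Patient John` would drag the common noun
  into the exclusion.
* **Whitelist.** Union of medical vocabulary and common English words,
  minus every blacklist name, plus explicit add-backs (ambiguous words
  like "white" that must stay retrievable as ordinary words while their
  proper-noun uses are caught by the gate). Numeric-tagged tokens never
  pass through it — an unexplained number is always obfuscated.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `surname_min_count` | 100 | census-style frequency cut for surnames |
| `firstname_min_count` | 5 | per-birth-year frequency cut for first names |
| `birth_year_range` | 1879–2017 | birth years scanned for first names |
| age `threshold` | 90 | lowest age treated as PHI (Safe Harbor) |
| age `context_radius` | 2 tokens | distance at which a trigger word counts |
| adjacency `radius` | 1 token | "adjacent" for name-context/initials |
| `obfuscation_char` | `*` | replacement character; length preserved |

The stage order itself is a parameter (the JSON `stages` array); the
shipped default is the order listed in the README, and the config
validator refuses pipelines whose blacklist/whitelist stages precede POS
tagging.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` builds notes from clinical-flavoured sentence
templates with PHI slots, one global seed, no hidden entropy. Per note
and category the instance count is Binomial(8, mix/8), so corpus totals
have a known sampling law (used by the tests as a 3σ bound). Realizers
cover the full default taxonomy and reproduce the failure modes that
matter for a rule cascade: several date formats, formatted and bare
identifiers, names drawn from the fixture frequency tables, a
configurable fraction of surnames from the name/common-word overlap pool
("White", "Young", …), misspelled names at a configurable rate, and
initials layouts. Gold spans are exact character intervals written in
the MAE-style XML dialect, so tests exercise the real reader path.

The generator does **not** model real clinical language: no narrative
structure, no OCR noise, no institution-specific formats, no
distributional realism. Passing tests on synthetic corpora demonstrate
that the machinery is sound (the evaluator's oracle fixed point, the
safety-net guarantee, determinism) and that the cascade behaves as
designed on the emulated failure modes. They do not estimate recall on
any real corpus, and no number computed here should be quoted as a
performance claim for real notes.

## Numerical and degenerate-input choices

* Empty note → empty token list, empty output; zero-width spans select
  no tokens; a span partially covering a token selects all of it.
* Recall is `NA` when a note has no gold PHI (not 0); F2 is undefined
  when `4P + R = 0` and errors in `f2_score()`, while the metrics
  container carries `NA` instead.
* Metrics are micro-averaged (counts summed, then divided); a macro
  flag reports unweighted per-note means but is not the default.
* Absurd numeric tokens that do not parse are skipped by the age rule
  with a warning rather than guessed at.
* Report printing rounds to two decimals; computation is unrounded. A
  consequence worth knowing: an F2 recomputed from precision/recall that
  were themselves rounded to two decimals can differ from an F2 computed
  on unrounded values by up to one unit in the last printed digit.
* The test suite's problem sizes — 10,000 random documents for the
  obfuscation fuzz, a 200-note synthetic corpus for evaluator soundness,
  1,000 random toy tables for threshold monotonicity — were chosen to
  exercise the properties thoroughly while keeping a full run around
  twenty seconds.

## Known limitations

* **Initials after the whitelist.** With the default stage order the
  whitelist runs before the initials stage, and single capital letters
  like `A` are both in the common-word vocabulary and tagged as proper
  nouns mid-sentence. Under global first-writer-wins, `Doe, A.` can
  leave the `A` retained. This is an honest consequence of the
  published stage order plus strict non-overwriting; initials are
  correspondingly the categories where synthetic leakage concentrates.
  Moving the initials stage before the whitelist in the config removes
  the leak at a precision cost.
* **Capitalised safe words.** Facility and organisation words
  ("Medical Center") that sit inside provider-location PHI are often
  whitelist members; they leak as token instances of that category —
  the same category-shaped weakness rule cascades show on real data.
* **Patient/provider attribution** of detected names is not attempted.
* The alignment-recovery adapter for external tools is a greedy
  token-sequence matcher, adequate for comparison but not exact.

## Reproducibility

Every stochastic component (the generator, test fuzzers) runs under an
explicit seed; pipeline execution itself is fully deterministic, and
per-note independence makes corpus runs order- and
scheduling-insensitive. `scripts/acceptance.R --seed N --out PATH`
recomputes the headline F2 summary values with the installed package and
writes them as JSON.
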