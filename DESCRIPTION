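Package: phifilter
Title: Rule-Based De-Identification of Free-Text Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An ordered, configuration-driven cascade for removing Protected
    Health Information (PHI) from free-text clinical notes: safe and PHI
    regular-expression stages, part-of-speech-gated name blacklists built
    from census-style surname and Social-Security-style first-name frequency
    tables, a safe-word whitelist acting as a privacy safety net, and an
    initials detector.  Obfuscation preserves character alignment so every
    output note has exactly the length and structure of its input.  Includes
    a character-aligned token-level evaluation framework (recall, precision,
    F2, per-category PHI leakage reports) with readers for MAE-style and
    i2b2-2014-style gold-standard XML, and a seeded synthetic annotated-note
    generator so the whole system can be developed and tested without access
    to any protected corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    optparse,
    stringi,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
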