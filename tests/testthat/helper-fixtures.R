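# Shared fixtures built in code at test time.

# Default pipeline config, parsed once per test run.
default_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- default_pipeline_config()
    cfg
  }
})

# A tiny POS-tagged token stream for filter-stage tests.
tagged_tokens <- function(text) {
  doc <- note_document(text)
  pos_tag(doc, tokenize(doc))
}

toy_last_names <- function() lexicon(c("White", "Doe", "Smith"))
toy_first_names <- function() lexicon(c("Jane", "John"))

# Obfuscated character test: which characters of the output are asterisks.
obfuscated_chars <- function(out) strsplit(out, "", fixed = TRUE)[[1]] == "*"

# Random printable text including separators, asterisks and digits.
random_text <- function(n_chars) {
  alphabet <- c(letters, LETTERS, 0:9, " ", " ", " ", "-", "/", "#", "&",
                ".", ",", ":", ";", "(", ")", "'", "\"", "*", "\n")
  paste(sample(alphabet, n_chars, replace = TRUE), collapse = "")
}
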