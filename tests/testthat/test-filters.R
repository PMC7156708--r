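safe_lib <- regex_library(data.frame(
  pattern = "(?i)\\b[0-9]+(?:\\.[0-9]+)?\\s?mg\\b",
  polarity = "SAFE", category = "NONE", description = "dosage"))

phi_lib <- regex_library(data.frame(
  pattern = c("\\b[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}\\b",
              "\\b[0-9]{3}-[0-9]{2}-[0-9]{4}\\b"),
  polarity = "PHI",
  category = c("Email", "Patient_Social_Security_Number"),
  description = c("email", "ssn")))

test_that("safe patterns mark intersecting unmarked tokens for inclusion", {
  doc <- note_document("take 50 mg now")
  tok <- apply_safe_regex(doc, tokenize(doc), safe_lib)
  expect_equal(tok$label[tok$surface %in% c("50", "mg")],
               c("INCLUDE", "INCLUDE"))
  expect_equal(tok$label[tok$surface == "now"], "UNMARKED")

  # first-writer-wins: an EXCLUDE set earlier survives a safe match
  tok2 <- tokenize(doc)
  tok2$label[2] <- "EXCLUDE"; tok2$stage[2] <- "earlier"
  tok2 <- apply_safe_regex(doc, tok2, safe_lib)
  expect_equal(tok2$label[2], "EXCLUDE")
  expect_equal(tok2$stage[2], "earlier")

  # empty library is the identity
  empty <- regex_library(data.frame(pattern = character(0),
                                    polarity = character(0),
                                    category = character(0)))
  expect_identical(apply_safe_regex(doc, tokenize(doc), empty),
                   tokenize(doc))
  expect_error(apply_safe_regex(doc, tokenize(doc), phi_lib), "SAFE")
})

test_that("PHI patterns exclude intersecting tokens with their category", {
  doc <- note_document("email jsmith@example.org ssn 123-45-6789 end")
  tok <- apply_phi_regex(doc, tokenize(doc), phi_lib)
  email_tok <- tok[tok$surface %in% c("jsmith", "example", "org"), ]
  expect_true(all(email_tok$label == "EXCLUDE"))
  expect_true(all(email_tok$category == "Email"))
  ssn_tok <- tok[tok$surface %in% c("123", "45", "6789"), ]
  expect_true(all(ssn_tok$label == "EXCLUDE"))
  expect_true(all(ssn_tok$category == "Patient_Social_Security_Number"))
  expect_true(all(tok$label[tok$surface %in% c("email", "ssn", "end")] ==
                    "UNMARKED"))

  # no matches: identity
  doc2 <- note_document("nothing here")
  expect_identical(apply_phi_regex(doc2, tokenize(doc2), phi_lib),
                   tokenize(doc2))
})

test_that("age rule excludes >= 90, includes < 90, ignores dosages", {
  doc <- note_document("age 92 noted")
  tok <- apply_age_rule(doc, tokenize(doc))
  expect_equal(tok$label[tok$surface == "92"], "EXCLUDE")
  expect_equal(tok$category[tok$surface == "92"], "Age >= 90")

  doc <- note_document("age 89 noted")
  tok <- apply_age_rule(doc, tokenize(doc))
  expect_equal(tok$label[tok$surface == "89"], "INCLUDE")

  # "50 mg": the dosage was already marked safe, the age rule leaves it be
  doc <- note_document("took 50 mg at age 91")
  tok <- apply_safe_regex(doc, tokenize(doc), safe_lib)
  tok <- apply_age_rule(doc, tok)
  expect_equal(tok$stage[tok$surface == "50"], "safe_regex")
  expect_equal(tok$label[tok$surface == "91"], "EXCLUDE")

  # a number with no age trigger nearby is untouched
  doc <- note_document("room 92 is ready")
  tok <- apply_age_rule(doc, tokenize(doc))
  expect_equal(tok$label[tok$surface == "92"], "UNMARKED")
})

test_that("rule tagger distinguishes proper-noun and adjective uses", {
  tok <- tagged_tokens("Patient John White presents with pain")
  expect_equal(tok$pos_tag[tok$surface == "White"], "NNP")
  expect_equal(tok$pos_tag[tok$surface == "John"], "NNP")
  expect_equal(tok$pos_tag[tok$surface == "Patient"], "NN")

  tok <- tagged_tokens("White fluid found at the site")
  expect_equal(tok$pos_tag[tok$surface == "White"], "JJ")

  expect_equal(tagged_tokens("92 years")$pos_tag, c("CD", "NNS"))

  # a tagger violating the length contract is a hard error
  bad_tagger <- function(doc, tokens) "NN"
  doc <- note_document("two tokens")
  expect_error(pos_tag(doc, tokenize(doc), bad_tagger), "contract")
})

test_that("name blacklist requires both membership and the NNP gate", {
  tok <- tagged_tokens("Patient John White presents")
  tok <- apply_name_blacklist(tok, toy_first_names(), toy_last_names())
  expect_equal(tok$label[tok$surface == "White"], "EXCLUDE")
  expect_equal(tok$category[tok$surface == "White"], "Name")
  expect_equal(tok$label[tok$surface == "John"], "EXCLUDE")
  expect_equal(tok$label[tok$surface == "Patient"], "UNMARKED")

  # adjective use: in the blacklist but not NNP, so untouched
  tok <- tagged_tokens("White fluid found at the site")
  tok <- apply_name_blacklist(tok, toy_first_names(), toy_last_names())
  expect_equal(tok$label[tok$surface == "White"], "UNMARKED")

  # NNP token not in any blacklist is untouched
  tok <- tagged_tokens("Seen by Zorblax today")
  tok <- apply_name_blacklist(tok, toy_first_names(), toy_last_names())
  expect_equal(tok$label[tok$surface == "Zorblax"], "UNMARKED")

  # running before the tagger is a stage-ordering violation
  doc <- note_document("John here")
  expect_error(apply_name_blacklist(tokenize(doc), toy_first_names(), NULL),
               "POS tags")
})

name_ctx_lib <- read_regex_library(
  system.file("extdata", "name_context_regex.tsv", package = "phifilter"))

test_that("name context fires only next to a blacklist exclusion", {
  doc <- note_document("Seen with Jane Doe today")
  tok <- pos_tag(doc, tokenize(doc))
  tok <- apply_name_blacklist(tok, toy_first_names(), NULL,
                              stage = "first_name_blacklist")
  expect_equal(tok$label[tok$surface == "Jane"], "EXCLUDE")
  tok <- apply_name_context(doc, tok, name_ctx_lib)
  expect_equal(tok$label[tok$surface == "Doe"], "EXCLUDE")

  # same text, no blacklist hit: pattern matches but nothing is marked
  tok2 <- pos_tag(doc, tokenize(doc))
  tok2 <- apply_name_context(doc, tok2, name_ctx_lib)
  expect_true(all(tok2$label == "UNMARKED"))

  # match at document start: only right adjacency exists, no error
  doc3 <- note_document("Jane Doe was seen")
  tok3 <- pos_tag(doc3, tokenize(doc3))
  tok3 <- apply_name_blacklist(tok3, NULL, toy_last_names(),
                               stage = "last_name_blacklist")
  tok3 <- apply_name_context(doc3, tok3, name_ctx_lib)
  expect_equal(tok3$label[tok3$surface == "Jane"], "EXCLUDE")
})

test_that("whitelist includes members, skips numerics, leaves the rest", {
  wl <- lexicon(c("aspirin", "daily", "took"))
  tok <- tagged_tokens("took aspirin 92 Xq9z daily")
  tok <- apply_whitelist(tok, wl)
  expect_equal(tok$label[tok$surface == "aspirin"], "INCLUDE")
  expect_equal(tok$label[tok$surface == "took"], "INCLUDE")
  # numeric POS tag: never passed through the whitelist
  expect_equal(tok$label[tok$surface == "92"], "UNMARKED")
  # unknown token: stays unmarked, i.e. will be obfuscated (safety net)
  expect_equal(tok$label[tok$surface == "Xq9z"], "UNMARKED")
  expect_error(apply_whitelist(tokenize(note_document("a b")), wl),
               "POS tags")
})

initials_lib <- read_regex_library(
  system.file("extdata", "initials_regex.tsv", package = "phifilter"))

test_that("initials are excluded only beside a blacklist exclusion", {
  run_bl <- function(text) {
    doc <- note_document(text)
    tok <- pos_tag(doc, tokenize(doc))
    tok <- apply_name_blacklist(tok, toy_first_names(), toy_last_names(),
                                stage = "last_name_blacklist")
    list(doc = doc, tok = tok)
  }
  x <- run_bl("Signed Doe, J. today")
  tok <- apply_initials(x$doc, x$tok, initials_lib)
  expect_equal(tok$label[tok$surface == "J"], "EXCLUDE")
  expect_equal(tok$category[tok$surface == "J"], "Initials")

  x <- run_bl("Seen Jane S. Doe today")
  tok <- apply_initials(x$doc, x$tok, initials_lib)
  expect_equal(tok$label[tok$surface == "S"], "EXCLUDE")

  # isolated initials with no blacklist neighbour: condition not met
  x <- run_bl("Exhibit Q. R. noted")
  tok <- apply_initials(x$doc, x$tok, initials_lib)
  expect_true(all(tok$label[tok$surface %in% c("Q", "R")] == "UNMARKED"))
})

test_that("labelling is monotone across any stage sequence", {
  doc <- note_document(paste(
    "Patient Jane Doe age 92 took 50 mg daily.",
    "Reach jsmith@example.org or 123-45-6789. Signed Doe, J."))
  tok <- tokenize(doc)
  stages <- list(
    function(t) apply_safe_regex(doc, t, safe_lib),
    function(t) apply_phi_regex(doc, t, phi_lib),
    function(t) apply_age_rule(doc, t),
    function(t) pos_tag(doc, t),
    function(t) apply_name_blacklist(t, toy_first_names(), toy_last_names(),
                                     stage = "last_name_blacklist"),
    function(t) apply_name_context(doc, t, name_ctx_lib),
    function(t) apply_whitelist(t, lexicon(c("took", "daily", "age"))),
    function(t) apply_initials(doc, t, initials_lib))
  for (st in stages) {
    before <- tok$label
    tok <- st(tok)
    changed <- before != tok$label
    expect_true(all(before[changed] == "UNMARKED"))
    expect_lte(sum(tok$label == "UNMARKED"), sum(before == "UNMARKED"))
  }
})

test_that("stage order only changes tokens matched by both polarities", {
  # "92" matches a SAFE dosage pattern ("92 mg") and the age rule; order
  # decides its fate, while tokens matched by only one stage are stable.
  doc <- note_document("age 92 mg noted")
  tok_sf <- apply_age_rule(doc, apply_safe_regex(doc, tokenize(doc),
                                                 safe_lib))
  tok_fs <- apply_safe_regex(doc, apply_age_rule(doc, tokenize(doc)),
                             safe_lib)
  expect_equal(tok_sf$label[tok_sf$surface == "92"], "INCLUDE")
  expect_equal(tok_fs$label[tok_fs$surface == "92"], "EXCLUDE")
  expect_equal(tok_sf$label[tok_sf$surface == "noted"],
               tok_fs$label[tok_fs$surface == "noted"])
})
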