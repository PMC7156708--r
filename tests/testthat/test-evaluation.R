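write_tmp_xml <- function(lines) {
  path <- withr::local_tempfile(fileext = ".xml",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("MAE-style gold files parse to offset spans", {
  path <- write_tmp_xml(c(
    '<DeidGold text_file="note1.txt">',
    '<TEXT><![CDATA[Seen on 07/14/2012 today.]]></TEXT>',
    '<TAGS>',
    '<Date id="P0" spans="8~18" text="07/14/2012" />',
    '</TAGS>',
    '</DeidGold>'))
  gold <- read_gold(path, "mae")
  expect_equal(gold$note_id, "note1")
  expect_equal(gold$spans$start, 8L)
  expect_equal(gold$spans$end, 18L)
  expect_equal(gold$spans$category, "Date")

  # zero annotations
  path <- write_tmp_xml(c('<DeidGold><TAGS></TAGS></DeidGold>'))
  expect_equal(nrow(read_gold(path, "mae")$spans), 0L)

  # overlapping spans merge on load
  path <- write_tmp_xml(c(
    '<DeidGold><TAGS>',
    '<Provider_Name id="P0" spans="0~8" />',
    '<Provider_Name id="P1" spans="5~12" />',
    '</TAGS></DeidGold>'))
  gold <- read_gold(path, "mae")
  expect_equal(nrow(gold$spans), 1L)
  expect_equal(gold$spans$end, 12L)

  # malformed XML is a hard error naming the file
  path <- write_tmp_xml("<unclosed")
  expect_error(read_gold(path, "mae"), "malformed XML")

  # unknown categories register dynamically with a warning
  path <- write_tmp_xml(c('<R><TAGS><Oddity spans="0~2"/></TAGS></R>'))
  expect_warning(gold <- read_gold(path, "mae"), "unknown PHI category")
  expect_true("Oddity" %in% phi_categories())
})

test_that("i2b2-style gold files parse TYPE/start/end attributes", {
  path <- write_tmp_xml(c(
    '<deIdi2b2><TEXT><![CDATA[Record of 2012 winter.]]></TEXT>',
    '<TAGS>',
    '<DATE id="P0" start="10" end="14" text="2012" TYPE="DATE" />',
    '<DATE id="P1" start="15" end="21" text="winter" TYPE="DATE" />',
    '</TAGS></deIdi2b2>'))
  expect_warning(gold <- read_gold(path, "i2b2"), "unknown PHI category")
  expect_equal(gold$spans$start, c(10L, 15L))
  expect_equal(gold$spans$category, c("DATE", "DATE"))
})

test_that("i2b2 normalisation retains Safe-Harbor PHI only", {
  text <- paste0("In 2012 during winter on Monday the patient from Canada ",
                 "aged 87 was seen on 07/14/2012 with id 1234 present.")
  doc <- note_document(text, "n1")
  find_span <- function(s) {
    st <- regexpr(s, text, fixed = TRUE)
    c(st - 1L, st - 1L + nchar(s))
  }
  spans <- rbind(
    data.frame(t(find_span("2012")), category = "DATE"),
    data.frame(t(find_span("winter")), category = "DATE"),
    data.frame(t(find_span("Monday")), category = "DATE"),
    data.frame(t(find_span("Canada")), category = "COUNTRY"),
    data.frame(t(find_span("87")), category = "AGE"),
    data.frame(t(find_span("07/14/2012")), category = "DATE"),
    data.frame(t(find_span("1234")), category = "IDNUM"))
  names(spans) <- c("start", "end", "category")
  for (cat_ in unique(spans$category)) {
    if (!cat_ %in% phi_categories()) register_phi_category(cat_)
  }
  gold <- gold_annotation("n1", spans, "i2b2")
  norm <- normalize_i2b2_gold(gold, doc)
  # only the full date survives: the isolated year, season, weekday,
  # country, age under 90 and 4-digit surrogate id are re-labelled safe
  expect_equal(nrow(norm$spans), 1L)
  expect_equal(substr(text, norm$spans$start + 1, norm$spans$end),
               "07/14/2012")

  # an age of 90 or more stays PHI
  doc2 <- note_document("patient aged 93 today", "n2")
  gold2 <- gold_annotation("n2", data.frame(
    start = 13L, end = 15L, category = "AGE"), "i2b2")
  expect_equal(nrow(normalize_i2b2_gold(gold2, doc2)$spans), 1L)

  # single letter with no adjacent gold content is dropped; one adjacent
  # to a gold name is kept
  doc3 <- note_document("exhibit Q filed; Smith J attending", "n3")
  gold3 <- gold_annotation("n3", data.frame(
    start = c(8L, 17L, 23L), end = c(9L, 22L, 24L),
    category = c("DOCTOR", "DOCTOR", "DOCTOR")), "i2b2")
  if (!"DOCTOR" %in% phi_categories()) register_phi_category("DOCTOR")
  norm3 <- normalize_i2b2_gold(gold3, doc3)
  kept <- substring(doc3$text, norm3$spans$start + 1, norm3$spans$end)
  expect_setequal(kept, c("Smith", "J"))
})

test_that("token-level contingency counts match a by-hand oracle", {
  # 20 tokens, the first 10 are gold PHI; the system obfuscates gold
  # tokens 1..9 plus safe tokens 11..13: recall 90, precision 75
  words <- sprintf("w%02d", 1:20)
  text <- paste(words, collapse = " ")
  doc <- note_document(text, "toy")
  tok <- tokenize(doc)
  gold <- gold_annotation("toy", data.frame(
    start = tok$start[1:10], end = tok$end[1:10],
    category = "Patient_Name_or_Family_Member_Name"), "mae")
  tok$label <- "INCLUDE"
  tok$label[c(1:9, 11:13)] <- "EXCLUDE"
  out <- obfuscate(doc, tok)
  m <- evaluate_note(doc, out, gold)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(9L, 3L, 1L, 7L))
  expect_equal(m$recall, 90)
  expect_equal(m$precision, 75)
  expect_equal(m$n_tokens, 20L)
  expect_equal(m$per_category_fn$Patient_Name_or_Family_Member_Name, 1L)

  # perfect output
  tok$label <- ifelse(seq_len(20) <= 10, "EXCLUDE", "INCLUDE")
  m <- evaluate_note(doc, obfuscate(doc, tok), gold)
  expect_equal(m$recall, 100)
  expect_equal(m$precision, 100)

  # null filter: output identical to input
  m <- evaluate_note(doc, doc$text, gold)
  expect_equal(m$tp, 0L)
  expect_equal(m$fp, 0L)
  expect_equal(m$recall, 0)

  # length mismatch breaks alignment
  expect_error(evaluate_note(doc, paste0(doc$text, "x"), gold),
               "alignment")
})

test_that("F2 arithmetic and its interpolation properties hold", {
  expect_equal(f2_score(50, 50), 50)
  expect_equal(f2_score(100, 100), 100)
  expect_error(f2_score(0, 0), "undefined")
  expect_error(f2_score(101, 50))

  set.seed(11)
  for (rep in 1:200) {
    p <- runif(1, 1, 100); r <- runif(1, 1, 100)
    f2 <- f2_score(p, r)
    f1 <- 2 * p * r / (p + r)
    expect_gte(f2, min(p, r) - 1e-9)
    expect_lte(f2, max(p, r) + 1e-9)
    # F2 is closer to recall than F1 is
    expect_lte(abs(f2 - r), abs(f1 - r) + 1e-9)
  }
})

test_that("corpus report micro-averages by summed counts", {
  m1 <- phifilter:::metrics_result(1, 0, 5, 1,
                                   per_category_fn = list(Date = 1L))
  m2 <- phifilter:::metrics_result(3, 1, 4, 0,
                                   per_category_fn = list())
  corp <- corpus_report(list(m1, m2))
  expect_equal(corp$recall, 80)                  # 4 / (4 + 1)
  expect_equal(corp$tp, 4)
  expect_equal(corp$per_category_fn$Date, 1L)
  expect_equal(corp$n_tokens, m1$n_tokens + m2$n_tokens)

  # single note: corpus equals note metrics
  solo <- corpus_report(list(m1))
  expect_equal(solo$recall, m1$recall)
  expect_equal(solo$precision, m1$precision)

  # macro flag reports unweighted means alongside
  corp <- corpus_report(list(m1, m2), macro = TRUE)
  expect_equal(corp$macro_recall, mean(c(50, 100)))
})

test_that("alignment-recovery adapter rebuilds comparable output", {
  doc <- note_document("Jane Doe seen for fever today")
  external <- "seen for fever today"   # a tool that dropped the name
  out <- realign_output(doc, external)
  expect_equal(nchar(out), doc$length)
  m <- evaluate_note(doc, out, gold_annotation("note", data.frame(
    start = 0L, end = 8L,
    category = "Patient_Name_or_Family_Member_Name"), "mae"))
  expect_equal(m$recall, 100)
  expect_equal(m$precision, 100)
})
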