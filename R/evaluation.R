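#' Gold-standard annotations
#'
#' Category-labelled character spans parsed from annotation XML.  Two
#' dialects are supported: MAE-style files (a `<TAGS>` block whose child
#' elements are named after the PHI category and carry `spans="start~end"`
#' attributes) and i2b2-2014-style files (child elements with `start`,
#' `end` and `TYPE` attributes).  Offsets are converted to the internal
#' 0-based half-open convention; overlapping spans are merged on load.
#'
#' @param note_id Note identifier.
#' @param spans Data frame with columns `start`, `end`, `category`.
#' @param source_dialect `"mae"` or `"i2b2"`.
#' @return An object of class `gold_annotation`.
#' @export
gold_annotation <- function(note_id, spans, source_dialect = "mae") {
  stopifnot(is.data.frame(spans),
            all(c("start", "end", "category") %in% names(spans)))
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  spans <- merge_overlapping_spans(spans)
  rownames(spans) <- NULL
  structure(list(note_id = note_id, spans = spans,
                 source_dialect = source_dialect),
            class = "gold_annotation")
}

merge_overlapping_spans <- function(spans) {
  if (nrow(spans) < 2L) return(spans)
  keep <- spans[1, , drop = FALSE]
  for (i in 2:nrow(spans)) {
    last <- nrow(keep)
    if (spans$start[i] < keep$end[last]) {
      keep$end[last] <- max(keep$end[last], spans$end[i])
    } else {
      keep <- rbind(keep, spans[i, , drop = FALSE])
    }
  }
  keep
}

#' @export
print.gold_annotation <- function(x, ...) {
  cat(sprintf("<gold_annotation '%s' (%s): %d spans>\n",
              x$note_id, x$source_dialect, nrow(x$spans)))
  invisible(x)
}

#' Read a gold-standard annotation file
#'
#' @param path Path to the XML file.
#' @param dialect `"mae"` or `"i2b2"`.
#' @return A [gold_annotation].  Unknown categories are registered
#'   dynamically with a warning; malformed XML is a hard error naming the
#'   file.
#' @export
read_gold <- function(path, dialect = c("mae", "i2b2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("gold file not found: ", path)
  xml <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e)))
  tags <- xml2::xml_find_first(xml, ".//TAGS")
  children <- if (inherits(tags, "xml_missing")) list() else
    xml2::xml_children(tags)
  n <- length(children)
  start <- integer(0); end <- integer(0); category <- character(0)
  for (node in children) {
    if (dialect == "mae") {
      spans_attr <- xml2::xml_attr(node, "spans")
      if (!is.na(spans_attr)) {
        parts <- as.integer(strsplit(spans_attr, "~", fixed = TRUE)[[1]])
        s <- parts[1]; e <- parts[2]
      } else {
        s <- as.integer(xml2::xml_attr(node, "start"))
        e <- as.integer(xml2::xml_attr(node, "end"))
      }
      type <- xml2::xml_attr(node, "type")
      cat_ <- if (!is.na(type)) type else xml2::xml_name(node)
    } else {
      s <- as.integer(xml2::xml_attr(node, "start"))
      e <- as.integer(xml2::xml_attr(node, "end"))
      cat_ <- xml2::xml_attr(node, "TYPE")
      if (is.na(cat_)) cat_ <- xml2::xml_name(node)
    }
    if (is.na(s) || is.na(e)) next
    if (!cat_ %in% phi_categories()) {
      warning("unknown PHI category '", cat_, "' registered from ", path)
      register_phi_category(cat_)
    }
    start <- c(start, s); end <- c(end, e); category <- c(category, cat_)
  }
  note_id <- xml2::xml_attr(xml2::xml_root(xml), "text_file")
  if (is.na(note_id)) {
    note_id <- tools::file_path_sans_ext(basename(path))
  } else {
    note_id <- tools::file_path_sans_ext(note_id)
  }
  gold_annotation(note_id,
                  data.frame(start = start, end = end, category = category,
                             stringsAsFactors = FALSE),
                  source_dialect = dialect)
}

#' Write a gold annotation in the MAE-style dialect
#'
#' Used by the synthetic-note generator so that the real reader path is
#' exercised in tests.  The note text is embedded in a `<TEXT>` CDATA
#' block; each span becomes a child of `<TAGS>` named after its category
#' (non-alphanumeric characters mapped to `_`), with a `spans="start~end"`
#' attribute and the original category in a `type` attribute.
#'
#' @param gold A [gold_annotation].
#' @param text The note text.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gold_mae <- function(gold, text, path) {
  doc <- xml2::xml_new_root("DeidGold", text_file = paste0(gold$note_id,
                                                              ".txt"))
  txt <- xml2::xml_add_child(doc, "TEXT")
  xml2::xml_add_child(txt, xml2::xml_cdata(text))
  tags <- xml2::xml_add_child(doc, "TAGS")
  for (i in seq_len(nrow(gold$spans))) {
    el <- gsub("[^A-Za-z0-9]+", "_", gold$spans$category[i])
    el <- sub("_+$", "", el)
    xml2::xml_add_child(
      tags, el,
      id = sprintf("P%d", i - 1L),
      spans = sprintf("%d~%d", gold$spans$start[i], gold$spans$end[i]),
      type = gold$spans$category[i],
      text = substr(text, gold$spans$start[i] + 1L, gold$spans$end[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Re-annotate i2b2-style gold to HIPAA Safe Harbor scope
#'
#' The i2b2 2014 annotations mark some words as PHI that Safe Harbor does
#' not require removing.  This normalisation re-labels the following span
#' classes from PHI to safe (removes them from the gold): years in
#' isolation, season words, days of the week, single letters with no
#' adjacent gold content (no gold-PHI token within stream distance 1),
#' country names, and ages under 90.  Surrogate patient identification
#' numbers of four digits or less — unrealistic surrogates — are also
#' removed.
#'
#' @param gold A [gold_annotation] with `source_dialect = "i2b2"`.
#' @param doc The [note_document] the annotations refer to.
#' @return A normalised [gold_annotation].
#' @export
normalize_i2b2_gold <- function(gold, doc) {
  stopifnot(inherits(gold, "gold_annotation"),
            inherits(doc, "note_document"))
  spans <- gold$spans
  if (!nrow(spans)) return(gold)
  surface <- trimws(substr(rep(doc$text, nrow(spans)),
                           spans$start + 1L, spans$end))
  lower <- tolower(surface)

  seasons <- c("winter", "spring", "summer", "fall", "autumn")
  weekdays_ <- c("monday", "tuesday", "wednesday", "thursday", "friday",
                 "saturday", "sunday", "mon", "tue", "tues", "wed", "thu",
                 "thurs", "fri", "sat", "sun")
  countries <- .country_list()

  tokens <- tokenize(doc)
  gold_tok <- rep(FALSE, nrow(tokens))
  for (i in seq_len(nrow(spans))) {
    gold_tok[span_to_tokens(tokens, spans$start[i], spans$end[i])] <- TRUE
  }

  drop <- rep(FALSE, nrow(spans))
  drop <- drop | grepl("^[12][0-9]{3}$", surface)            # isolated years
  drop <- drop | lower %in% seasons
  drop <- drop | lower %in% weekdays_
  drop <- drop | lower %in% countries
  # ages under 90
  is_age <- grepl("(?i)age", spans$category, perl = TRUE)
  age_val <- suppressWarnings(as.numeric(surface))
  drop <- drop | (is_age & !is.na(age_val) & age_val < 90)
  # short surrogate patient identification numbers (<= 4 digits)
  is_id <- grepl("(?i)idnum|medicalrecord|unique_id|account|record",
                 spans$category, perl = TRUE)
  drop <- drop | (is_id & grepl("^[0-9]{1,4}$", surface))
  # single letters with no adjacent gold content
  for (i in which(grepl("^[A-Za-z]$", surface))) {
    idx <- span_to_tokens(tokens, spans$start[i], spans$end[i])
    if (!length(idx)) next
    nb <- setdiff(seq(max(1L, min(idx) - 1L), min(nrow(tokens),
                                                  max(idx) + 1L)), idx)
    if (!any(gold_tok[nb])) drop[i] <- TRUE
  }

  gold_annotation(gold$note_id, spans[!drop, , drop = FALSE],
                  source_dialect = gold$source_dialect)
}

.country_list <- function() {
  path <- system.file("extdata", "countries.txt", package = "phifilter")
  tolower(readLines(path, warn = FALSE))
}

#' Token-level evaluation of one de-identified note
#'
#' The comparison is character-aligned (the output must have exactly the
#' input's character count) but scored at the word level: a token counts
#' as predicted-PHI iff any of its characters were obfuscated, and as
#' gold-PHI iff it intersects any gold span.  True positives are gold-PHI
#' tokens that were obfuscated; false positives are safe tokens that were
#' obfuscated; false negatives are gold-PHI tokens that leaked through;
#' true negatives are safe tokens retained.  Recall = TP/(TP+FN) and
#' precision = TP/(TP+FP), reported on the percentage scale.
#'
#' @param original The original [note_document].
#' @param deid_output The de-identified text (same character count).
#' @param gold A [gold_annotation] for the note.
#' @param obfuscation_char The obfuscation character used (default `"*"`).
#' @return A `metrics_result` list: `tp`, `fp`, `tn`, `fn`, `n_tokens`,
#'   `recall`, `precision`, `f2` (percent; `NA` where undefined) and
#'   `per_category_fn`, the count of PHI token instances remaining per
#'   gold category.
#' @export
evaluate_note <- function(original, deid_output, gold,
                          obfuscation_char = "*") {
  stopifnot(inherits(original, "note_document"))
  if (nchar(deid_output, type = "chars") != original$length) {
    stop("character alignment broken for note '", original$note_id,
         "': output length ", nchar(deid_output), " != input length ",
         original$length,
         " (use realign_output() for tools that do not preserve length)")
  }
  tokens <- tokenize(original)
  n <- nrow(tokens)
  out_chars <- strsplit(deid_output, "", fixed = TRUE)[[1]]
  predicted <- vapply(seq_len(n), function(i) {
    any(out_chars[(tokens$start[i] + 1L):tokens$end[i]] == obfuscation_char)
  }, logical(1))

  gold_flag <- rep(FALSE, n)
  token_category <- rep(NA_character_, n)
  for (i in seq_len(nrow(gold$spans))) {
    idx <- span_to_tokens(tokens, gold$spans$start[i], gold$spans$end[i])
    gold_flag[idx] <- TRUE
    token_category[idx] <- gold$spans$category[i]
  }

  tp <- sum(predicted & gold_flag)
  fp <- sum(predicted & !gold_flag)
  fn <- sum(!predicted & gold_flag)
  tn <- sum(!predicted & !gold_flag)
  leaked <- token_category[!predicted & gold_flag]
  per_category_fn <- if (length(leaked)) table(leaked) else
    table(character(0))
  metrics_result(tp, fp, tn, fn,
                 per_category_fn = as.list(per_category_fn))
}

metrics_result <- function(tp, fp, tn, fn, per_category_fn = list(),
                           n_notes = 1L) {
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  f2 <- if (!is.na(recall) && !is.na(precision) &&
              (4 * precision + recall) > 0) {
    f2_score(precision, recall)
  } else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_tokens = tp + fp + tn + fn,
                 recall = recall, precision = precision, f2 = f2,
                 per_category_fn = per_category_fn, n_notes = n_notes),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf(
    "<metrics_result: %d notes, %d tokens | TP %d FP %d TN %d FN %d>\n",
    x$n_notes, x$n_tokens, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  recall %.2f%%  precision %.2f%%  F2 %.2f%%\n",
              x$recall, x$precision, x$f2))
  invisible(x)
}

#' F2 score from precision and recall
#'
#' The weighted harmonic mean that values recall twice as much as
#' precision: `F2 = 5 * P * R / (4 * P + R)`, on the same percentage
#' scale as its inputs.  Recall is the privacy-critical metric in
#' de-identification, which is why the F-beta weighting favours it.
#'
#' @param precision,recall Percentages in `[0, 100]`, not both zero.
#' @return The F2 score as a percentage (unrounded; reports round to two
#'   decimals).
#' @examples
#' f2_score(precision = 78.58, recall = 99.92)
#' @export
f2_score <- function(precision, recall) {
  stopifnot(is.numeric(precision), is.numeric(recall),
            all(precision >= 0 & precision <= 100),
            all(recall >= 0 & recall <= 100))
  denom <- 4 * precision + recall
  if (any(denom == 0)) stop("F2 undefined: 4*precision + recall is zero")
  5 * precision * recall / denom
}

#' Micro-averaged corpus metrics and per-category leakage table
#'
#' Sums the per-note contingency counts and recomputes recall, precision
#' and F2 from the totals (micro-averaging), and aggregates the
#' per-category counts of PHI token instances remaining — the shape of a
#' remaining-PHI leakage report.  Categories with zero gold instances are
#' absent, not zero.
#'
#' @param per_note List of `metrics_result` objects (at least one).
#' @param macro If `TRUE`, additionally report the unweighted mean of
#'   per-note recall/precision (macro average) in `macro_recall` /
#'   `macro_precision`.
#' @return A `metrics_result` for the corpus; `per_category_fn` is the
#'   summed leakage table.
#' @export
corpus_report <- function(per_note, macro = FALSE) {
  stopifnot(length(per_note) >= 1)
  tp <- sum(vapply(per_note, `[[`, 0, "tp"))
  fp <- sum(vapply(per_note, `[[`, 0, "fp"))
  tn <- sum(vapply(per_note, `[[`, 0, "tn"))
  fn <- sum(vapply(per_note, `[[`, 0, "fn"))
  cats <- list()
  for (m in per_note) {
    for (nm in names(m$per_category_fn)) {
      cats[[nm]] <- (cats[[nm]] %||% 0L) + as.integer(m$per_category_fn[[nm]])
    }
  }
  res <- metrics_result(tp, fp, tn, fn, per_category_fn = cats,
                        n_notes = length(per_note))
  if (macro) {
    res$macro_recall <- mean(vapply(per_note, `[[`, 0, "recall"),
                             na.rm = TRUE)
    res$macro_precision <- mean(vapply(per_note, `[[`, 0, "precision"),
                                na.rm = TRUE)
  }
  res
}

#' Write a leakage/metrics report
#'
#' Emits the corpus metrics and the per-category remaining-PHI table as
#' TSV or JSON, numbers on the percentage scale rounded to two decimals.
#'
#' @param report A `metrics_result` from [corpus_report()].
#' @param path Output path ending in `.tsv` or `.json`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    out <- list(
      tp = report$tp, fp = report$fp, tn = report$tn, fn = report$fn,
      recall = round(report$recall, 2), precision = round(report$precision, 2),
      f2 = round(report$f2, 2), per_category_fn = report$per_category_fn)
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    lines <- c(
      "metric\tvalue",
      sprintf("recall\t%.2f", report$recall),
      sprintf("precision\t%.2f", report$precision),
      sprintf("f2\t%.2f", report$f2),
      "",
      "category\tinstances_remaining",
      vapply(names(report$per_category_fn), function(nm) {
        sprintf("%s\t%d", nm, as.integer(report$per_category_fn[[nm]]))
      }, ""))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Recover character alignment for external tool output
#'
#' Some de-identification tools do not preserve note length.  This
#' adapter matches the external output's token sequence against the
#' original note's tokens (greedy in-order matching) and rebuilds a
#' character-aligned output in which every original token absent from the
#' external output is obfuscated.  It is an approximation for comparing
#' third-party tools, not part of the core pipeline.
#'
#' @param original The original [note_document].
#' @param external_output The external tool's output text.
#' @param obfuscation_char Character to use when rebuilding.
#' @return A character-aligned de-identified text usable with
#'   [evaluate_note()].
#' @export
realign_output <- function(original, external_output,
                           obfuscation_char = "*") {
  tokens <- tokenize(original)
  ext <- tokenize(note_document(external_output, "external"))
  kept <- rep(FALSE, nrow(tokens))
  j <- 1L
  for (i in seq_len(nrow(tokens))) {
    if (j > nrow(ext)) break
    if (tokens$surface[i] == ext$surface[j]) {
      kept[i] <- TRUE
      j <- j + 1L
    }
  }
  tokens$label <- ifelse(kept, "INCLUDE", "EXCLUDE")
  obfuscate(original, tokens, obfuscation_char)
}
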