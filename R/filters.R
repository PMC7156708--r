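#' Cascade stages over the token stream
#'
#' Every detection stage obeys the same contract: it may transition a
#' token's label from `UNMARKED` to `EXCLUDE` or from `UNMARKED` to
#' `INCLUDE`, and it never overwrites a label set by an earlier stage
#' (first-writer-wins).  Stage priority is therefore exactly the order of
#' stages in the pipeline configuration.
#'
#' @name filters
NULL

#' Apply a library of safe patterns
#'
#' Short phrases with a high probability of not being PHI (dosages, lab
#' values, vital signs, ...) are matched on the raw note text; every
#' still-unmarked token intersecting a match is marked for inclusion.
#'
#' @param doc A [note_document].
#' @param tokens Token data frame.
#' @param library A [regex_library] whose entries all have polarity `SAFE`.
#' @param stage Stage name recorded as provenance.
#' @return Updated token data frame.
#' @export
apply_safe_regex <- function(doc, tokens, library, stage = "safe_regex") {
  stopifnot(inherits(library, "regex_library"))
  if (nrow(library) && !all(library$polarity == "SAFE")) {
    stop("apply_safe_regex requires a SAFE-polarity library")
  }
  for (i in seq_len(nrow(library))) {
    spans <- match_spans(library$pattern[i], doc$text)
    for (j in seq_len(nrow(spans))) {
      idx <- span_to_tokens(tokens, spans$start[j], spans$end[j])
      tokens <- mark_tokens(tokens, idx, "INCLUDE", stage = stage)
    }
  }
  tokens
}

#' Apply a library of PHI patterns
#'
#' Predictable PHI entities — salutations, emails, phone and fax numbers,
#' dates (including dates of birth), social security numbers, postal codes,
#' record numbers, URLs and IP addresses — are matched on the raw text;
#' every still-unmarked token intersecting a match is marked for exclusion
#' with the entry's category.  Partial character overlap excludes the whole
#' token.
#'
#' @inheritParams apply_safe_regex
#' @param library A [regex_library] whose entries all have polarity `PHI`.
#' @export
apply_phi_regex <- function(doc, tokens, library, stage = "phi_regex") {
  stopifnot(inherits(library, "regex_library"))
  if (nrow(library) && !all(library$polarity == "PHI")) {
    stop("apply_phi_regex requires a PHI-polarity library")
  }
  for (i in seq_len(nrow(library))) {
    spans <- match_spans(library$pattern[i], doc$text)
    for (j in seq_len(nrow(spans))) {
      idx <- span_to_tokens(tokens, spans$start[j], spans$end[j])
      tokens <- mark_tokens(tokens, idx, "EXCLUDE",
                            category = library$category[i], stage = stage)
    }
  }
  tokens
}

#' Age rule configuration
#'
#' @param trigger_words Context phrases whose tokens mark a neighbouring
#'   number as an age.
#' @param threshold Age at or above which the number is PHI (HIPAA Safe
#'   Harbor uses 90).
#' @param context_radius Token-stream distance within which a trigger
#'   counts as adjacent.
#' @return A list of class `age_rule_config`.
#' @export
age_rule_config <- function(trigger_words = c("age", "years old", "y.o."),
                            threshold = 90L, context_radius = 2L) {
  stopifnot(threshold >= 0, context_radius >= 1)
  structure(list(trigger_words = trigger_words,
                 threshold = as.integer(threshold),
                 context_radius = as.integer(context_radius)),
            class = "age_rule_config")
}

#' Mark ages at or above the threshold as PHI
#'
#' A numeric token within `context_radius` tokens of an age trigger word is
#' interpreted as an age: values at or above the threshold are excluded
#' with category `"Age >= 90"`, values below it are marked safe.  Numbers
#' already labelled by an earlier stage (for example dosages caught by the
#' safe-pattern library) are untouched.
#'
#' @param doc A [note_document].
#' @param tokens Token data frame.
#' @param cfg An [age_rule_config].
#' @param stage Stage name recorded as provenance.
#' @return Updated token data frame.
#' @export
apply_age_rule <- function(doc, tokens, cfg = age_rule_config(),
                           stage = "age_rule") {
  stopifnot(inherits(cfg, "age_rule_config"))
  n <- nrow(tokens)
  if (n == 0L) return(tokens)
  trigger_tokens <- unique(tolower(unlist(
    regmatches(cfg$trigger_words,
               gregexpr("[\\p{L}\\p{N}]+", cfg$trigger_words, perl = TRUE))
  )))
  lower <- tolower(tokens$surface)
  numeric_idx <- which(grepl("^[0-9]+$", tokens$surface) &
                         tokens$label == "UNMARKED")
  for (i in numeric_idx) {
    nb <- seq(max(1L, i - cfg$context_radius),
              min(n, i + cfg$context_radius))
    nb <- setdiff(nb, i)
    if (!any(lower[nb] %in% trigger_tokens)) next
    value <- suppressWarnings(as.numeric(tokens$surface[i]))
    if (is.na(value)) {
      warning("unparseable numeric token skipped by age rule: ",
              tokens$surface[i])
      next
    }
    if (value >= cfg$threshold) {
      tokens <- mark_tokens(tokens, i, "EXCLUDE", "Age >= 90", stage)
    } else {
      tokens <- mark_tokens(tokens, i, "INCLUDE", stage = stage)
    }
  }
  tokens
}

# Stages whose exclusions satisfy the "previously marked by a blacklist"
# adjacency condition of the name-context and initials stages.
is_blacklist_stage <- function(stage_names, blacklist_stages = NULL) {
  if (is.null(blacklist_stages)) {
    grepl("blacklist", stage_names, fixed = TRUE)
  } else {
    stage_names %in% blacklist_stages
  }
}

#' Apply a POS-gated name blacklist
#'
#' A still-unmarked token whose lowercase surface occurs in at least one of
#' the supplied name blacklists *and* whose POS tag is `NNP` (proper noun)
#' is excluded with the generic `Name` category.  The proper-noun gate is
#' what lets "White" survive as an adjective while being removed as a
#' surname.  Patient versus provider names cannot be distinguished at
#' detection time; the split onto gold categories happens in evaluation.
#'
#' @param tokens Token data frame; [pos_tag()] must have run.
#' @param first_names,last_names [lexicon] objects (either may be `NULL`).
#' @param stage Stage name; stages whose name contains `"blacklist"` feed
#'   the adjacency conditions of later name-context/initials stages.
#' @return Updated token data frame.
#' @export
apply_name_blacklist <- function(tokens, first_names = NULL,
                                 last_names = NULL,
                                 stage = "name_blacklist") {
  if (any(tokens$pos_tag == "UNSET")) {
    stop("POS tags are unset: run pos_tag() before the name blacklist stage")
  }
  members <- character(0)
  for (lex in list(first_names, last_names)) {
    if (!is.null(lex)) {
      stopifnot(inherits(lex, "lexicon"))
      members <- c(members, lex$tokens)
    }
  }
  if (!length(members)) return(tokens)
  hit <- which(tokens$label == "UNMARKED" & tokens$pos_tag == "NNP" &
                 tolower(tokens$surface) %in% members)
  mark_tokens(tokens, hit, "EXCLUDE", "Name", stage)
}

#' Apply name-context patterns
#'
#' A small library of patterns for common name layouts in clinical notes
#' ("Jane Doe", "Doe, Jane", "Jane S. Doe", hyphenated surnames) is matched
#' on the raw text.  Matched still-unmarked tokens are excluded with the
#' `Name` category if and only if an adjacent token (stream distance 1 by
#' default) was previously excluded by a blacklist stage.
#'
#' @param doc A [note_document].
#' @param tokens Token data frame.
#' @param patterns A [regex_library] of name patterns (polarity `PHI`).
#' @param blacklist_stages Stage names counting as blacklist provenance;
#'   `NULL` means any stage whose name contains `"blacklist"`.
#' @param radius Adjacency radius in tokens.
#' @param stage Stage name recorded as provenance.
#' @return Updated token data frame.
#' @export
apply_name_context <- function(doc, tokens, patterns,
                               blacklist_stages = NULL, radius = 1L,
                               stage = "name_context") {
  stopifnot(inherits(patterns, "regex_library"))
  n <- nrow(tokens)
  if (n == 0L) return(tokens)
  from_blacklist <- tokens$label == "EXCLUDE" &
    is_blacklist_stage(tokens$stage, blacklist_stages)
  for (i in seq_len(nrow(patterns))) {
    spans <- match_spans(patterns$pattern[i], doc$text)
    for (j in seq_len(nrow(spans))) {
      idx <- span_to_tokens(tokens, spans$start[j], spans$end[j])
      for (k in idx) {
        if (tokens$label[k] != "UNMARKED") next
        # when tags are available, only proper nouns are name candidates:
        # "Patient John ..." must not drag "Patient" (NN) into the match
        if (!tokens$pos_tag[k] %in% c("NNP", "NNPS", "UNSET")) next
        nb <- setdiff(seq(max(1L, k - radius), min(n, k + radius)), k)
        if (any(from_blacklist[nb])) {
          tokens <- mark_tokens(tokens, k, "EXCLUDE", "Name", stage)
        }
      }
    }
  }
  tokens
}

#' Apply the safe-word whitelist
#'
#' The safety net of the cascade: every still-unmarked token whose POS tag
#' is not numeric is looked up (lowercase) in the whitelist of medical and
#' common-English vocabulary.  Members are marked for inclusion;
#' non-members stay unmarked and are therefore obfuscated at final
#' disposition — unknown words are treated as potential PHI.  Numeric
#' tokens never pass through the whitelist.
#'
#' @param tokens Token data frame; [pos_tag()] must have run.
#' @param whitelist A [lexicon].
#' @param numeric_tags POS tags treated as numeric (default `"CD"`).
#' @param stage Stage name recorded as provenance.
#' @return Updated token data frame.
#' @export
apply_whitelist <- function(tokens, whitelist, numeric_tags = "CD",
                            stage = "whitelist") {
  stopifnot(inherits(whitelist, "lexicon"))
  if (any(tokens$pos_tag == "UNSET")) {
    stop("POS tags are unset: run pos_tag() before the whitelist stage")
  }
  hit <- which(tokens$label == "UNMARKED" &
                 !(tokens$pos_tag %in% numeric_tags) &
                 tolower(tokens$surface) %in% whitelist$tokens)
  mark_tokens(tokens, hit, "INCLUDE", stage = stage)
}

#' Detect patient and provider initials
#'
#' A single pattern library for initials layouts ("Doe, J.", "Jane S.
#' Doe", "J. D.") is matched on the raw text; matched still-unmarked
#' single-letter tokens are excluded with the `Initials` category if and
#' only if one or more adjacent tokens were previously excluded by a
#' blacklist stage.
#'
#' @inheritParams apply_name_context
#' @param patterns A [regex_library] of initials patterns.
#' @export
apply_initials <- function(doc, tokens, patterns, blacklist_stages = NULL,
                           radius = 1L, stage = "initials") {
  stopifnot(inherits(patterns, "regex_library"))
  n <- nrow(tokens)
  if (n == 0L) return(tokens)
  from_blacklist <- tokens$label == "EXCLUDE" &
    is_blacklist_stage(tokens$stage, blacklist_stages)
  single_letter <- grepl("^\\p{L}$", tokens$surface, perl = TRUE)
  for (i in seq_len(nrow(patterns))) {
    spans <- match_spans(patterns$pattern[i], doc$text)
    for (j in seq_len(nrow(spans))) {
      idx <- span_to_tokens(tokens, spans$start[j], spans$end[j])
      for (k in idx) {
        if (!single_letter[k] || tokens$label[k] != "UNMARKED") next
        nb <- setdiff(seq(max(1L, k - radius), min(n, k + radius)), k)
        if (any(from_blacklist[nb])) {
          tokens <- mark_tokens(tokens, k, "EXCLUDE", "Initials", stage)
        }
      }
    }
  }
  tokens
}
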