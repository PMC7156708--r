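#' Lexicons: name blacklists and the safe whitelist
#'
#' A lexicon is a set of lowercase, tokenizer-stable strings with build
#' metadata (sources, thresholds, exclusion list).  Membership tests are
#' exact-string and case-insensitive by prior normalisation: the cascade
#' lowercases token surfaces at comparison time, never the tokens
#' themselves (POS gating needs the original case).
#'
#' @param tokens Character vector of members; lowercased, tokenized and
#'   deduplicated on construction.  Multi-word entries are split and each
#'   part added separately.
#' @param meta Named list of build metadata.
#' @return An object of class `lexicon` with fields `tokens` (sorted
#'   character vector) and `meta`.
#' @export
lexicon <- function(tokens = character(0), meta = list()) {
  tokens <- tolower(as.character(tokens))
  # split multi-word entries the same way the tokenizer would
  parts <- unlist(regmatches(tokens,
                             gregexpr("[\\p{L}\\p{N}]+", tokens, perl = TRUE)))
  parts <- unique(parts[nzchar(parts)])
  structure(list(tokens = sort(parts), meta = meta), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d tokens>\n", length(x$tokens)))
  invisible(x)
}

#' @export
length.lexicon <- function(x) length(x$tokens)

#' Blacklist build configuration
#'
#' Defaults follow the published construction: surnames occurring 100 or
#' more times in a census-style frequency table; first names occurring
#' five or more times in at least one birth year between 1879 and 2017 in
#' a Social-Security-style table; a curated list of common-word names
#' removed afterwards.
#'
#' @param surname_min_count Minimum surname frequency (default 100).
#' @param firstname_min_count Minimum first-name frequency within a single
#'   birth year (default 5).
#' @param birth_year_range Inclusive year interval (default 1879--2017).
#' @param exclusion_words Safe words removed from the built blacklist.
#' @return A list of class `blacklist_build_config`.
#' @export
blacklist_build_config <- function(surname_min_count = 100L,
                                   firstname_min_count = 5L,
                                   birth_year_range = c(1879L, 2017L),
                                   exclusion_words = character(0)) {
  stopifnot(surname_min_count >= 1, firstname_min_count >= 1,
            length(birth_year_range) == 2,
            birth_year_range[1] <= birth_year_range[2])
  structure(list(surname_min_count = as.integer(surname_min_count),
                 firstname_min_count = as.integer(firstname_min_count),
                 birth_year_range = as.integer(birth_year_range),
                 exclusion_words = tolower(exclusion_words)),
            class = "blacklist_build_config")
}

#' Build the last-name blacklist from a surname frequency table
#'
#' @param census_rows Data frame with columns `surname` and `count`.
#' @param cfg A [blacklist_build_config].
#' @return A [lexicon] of lowercase surname tokens with count at or above
#'   the threshold, minus the exclusion words.
#' @export
build_last_name_blacklist <- function(census_rows,
                                      cfg = blacklist_build_config()) {
  stopifnot(is.data.frame(census_rows),
            all(c("surname", "count") %in% names(census_rows)))
  count <- suppressWarnings(as.numeric(census_rows$count))
  bad <- is.na(count) | count < 0 | is.na(census_rows$surname) |
    !nzchar(census_rows$surname)
  if (any(bad)) {
    warning(sum(bad), " malformed surname row(s) skipped")
  }
  keep <- !bad & count >= cfg$surname_min_count
  lex <- lexicon(census_rows$surname[keep])
  lex$tokens <- setdiff(lex$tokens, cfg$exclusion_words)
  lex$meta <- list(source = "surname frequency table",
                   min_count = cfg$surname_min_count,
                   n_excluded = length(cfg$exclusion_words))
  lex
}

#' Build the first-name blacklist from a birth-year frequency table
#'
#' A name qualifies when it reaches the minimum count in at least one
#' birth year inside the configured range; rows outside the range are
#' ignored.
#'
#' @param ssa_rows Data frame with columns `name`, `birth_year`, `count`.
#' @param cfg A [blacklist_build_config].
#' @return A [lexicon].
#' @export
build_first_name_blacklist <- function(ssa_rows,
                                       cfg = blacklist_build_config()) {
  stopifnot(is.data.frame(ssa_rows),
            all(c("name", "birth_year", "count") %in% names(ssa_rows)))
  count <- suppressWarnings(as.numeric(ssa_rows$count))
  year <- suppressWarnings(as.integer(ssa_rows$birth_year))
  bad <- is.na(count) | count < 0 | is.na(year) | is.na(ssa_rows$name) |
    !nzchar(ssa_rows$name)
  if (any(bad)) warning(sum(bad), " malformed first-name row(s) skipped")
  keep <- !bad &
    year >= cfg$birth_year_range[1] & year <= cfg$birth_year_range[2] &
    count >= cfg$firstname_min_count
  lex <- lexicon(ssa_rows$name[keep])
  lex$tokens <- setdiff(lex$tokens, cfg$exclusion_words)
  lex$meta <- list(source = "first-name-by-birth-year frequency table",
                   min_count = cfg$firstname_min_count,
                   birth_year_range = cfg$birth_year_range,
                   n_excluded = length(cfg$exclusion_words))
  lex
}

#' Build the safe whitelist from vocabulary sources
#'
#' The union of the supplied vocabularies (medical term banks, common
#' English words, abbreviations) is lowercased and tokenized; every token
#' that also occurs in any name blacklist is removed — names that double
#' as common words or medical terms must not ride into the whitelist —
#' and the `add_back` tokens are then re-inserted.  The number of
#' name/vocabulary overlaps removed is recorded in the metadata.
#'
#' @param vocab_sources List of character vectors.
#' @param name_blacklists List of [lexicon] objects to subtract.
#' @param add_back Tokens re-inserted after the subtraction.
#' @return A [lexicon]; `meta$n_overlap_removed` reports how many
#'   vocabulary tokens were dropped because they are also names.
#' @export
build_whitelist <- function(vocab_sources, name_blacklists = list(),
                            add_back = character(0)) {
  base <- lexicon(unlist(vocab_sources, use.names = FALSE))
  blacklist_tokens <- unique(unlist(lapply(name_blacklists,
                                           function(l) l$tokens)))
  overlap <- intersect(base$tokens, blacklist_tokens)
  tokens <- union(setdiff(base$tokens, blacklist_tokens),
                  lexicon(add_back)$tokens)
  out <- lexicon(tokens)
  out$meta <- list(source = "vocabulary union minus name blacklists",
                   n_sources = length(vocab_sources),
                   n_overlap_removed = length(overlap),
                   n_add_back = length(add_back),
                   size = length(out$tokens))
  # construction invariant: whitelist members also in a blacklist can only
  # have come from add_back
  residual <- intersect(out$tokens, blacklist_tokens)
  stopifnot(all(residual %in% lexicon(add_back)$tokens))
  out
}

#' Save and load lexicons
#'
#' One token per line, UTF-8, preceded by a `#`-prefixed header holding
#' the metadata as JSON.  The round trip preserves the token set and
#' metadata exactly; duplicate lines collapse under set semantics.
#'
#' @param lex A [lexicon].
#' @param path File path.
#' @return `load_lexicon` returns a [lexicon]; `save_lexicon` returns the
#'   path invisibly.
#' @export
save_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# meta: ",
                    jsonlite::toJSON(lex$meta, auto_unbox = TRUE)), con)
  writeLines(lex$tokens, con)
  invisible(path)
}

#' @rdname save_lexicon
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta <- list()
  header <- grepl("^#", lines)
  meta_line <- grep("^# meta: ", lines, value = TRUE)
  if (length(meta_line)) {
    meta <- jsonlite::fromJSON(sub("^# meta: ", "", meta_line[1]),
                               simplifyVector = TRUE)
  }
  lex <- lexicon(lines[!header & nzchar(lines)])
  lex$meta <- meta
  lex
}
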