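#' Part-of-speech tagging of the token stream
#'
#' Sets the `pos_tag` of every token.  The tagging contract is: a tagger is
#' a function `(doc, tokens) -> character vector` returning one
#' Penn-Treebank-style tag per token, in order.  Any tagger satisfying the
#' contract is pluggable; the package ships [rule_tagger()], a deterministic
#' context-aware tagger, so that the cascade's behaviour does not depend on
#' third-party statistical model versions.
#'
#' @param doc A [note_document].
#' @param tokens Token data frame from [tokenize()].
#' @param tagger A tagging function; defaults to [rule_tagger()].
#' @return `tokens` with `pos_tag` filled in; labels are unchanged.
#' @export
pos_tag <- function(doc, tokens, tagger = rule_tagger()) {
  tags <- tagger(doc, tokens)
  if (!is.character(tags) || length(tags) != nrow(tokens)) {
    stop("tagger returned ", length(tags), " tags for ", nrow(tokens),
         " tokens: contract violated")
  }
  tokens$pos_tag <- tags
  tokens
}

#' Deterministic rule-based POS tagger
#'
#' A context-aware fallback tagger over Penn Treebank tags.  Rules, in
#' order per token:
#' \enumerate{
#'   \item all digits: `CD`;
#'   \item lowercase form found in the shipped tag lexicon and the token is
#'     either uncapitalised or sentence-initial: the lexicon tag (this is
#'     what lets a sentence-initial "White" be read as the adjective rather
#'     than a proper noun);
#'   \item capitalised and not sentence-initial: `NNP`;
#'   \item capitalised, sentence-initial, unknown to the lexicon: `NNP`
#'     (privacy-conservative: unknown capitalised words look like names);
#'   \item otherwise `NN`.
#' }
#' A token is sentence-initial when it is the first token of the note or
#' the separator gap before it contains a sentence-ending character
#' (`.`, `!`, `?`, newline).
#'
#' @param lexicon_path Path to a two-column `word<TAB>tag` lexicon; defaults
#'   to the lexicon shipped with the package.
#' @return A tagger function usable with [pos_tag()].
#' @export
rule_tagger <- function(lexicon_path = NULL) {
  if (is.null(lexicon_path)) {
    lexicon_path <- system.file("extdata", "tagger_lexicon.tsv",
                                package = "phifilter")
  }
  lex <- utils::read.delim(lexicon_path, header = FALSE, comment.char = "#",
                           col.names = c("word", "tag"),
                           stringsAsFactors = FALSE)
  tagmap <- stats::setNames(lex$tag, tolower(lex$word))

  function(doc, tokens) {
    n <- nrow(tokens)
    if (n == 0L) return(character(0))
    surf <- tokens$surface
    lower <- tolower(surf)
    first_char <- substr(surf, 1L, 1L)
    capitalised <- first_char != lower & grepl("^\\p{Lu}", surf, perl = TRUE)
    all_digit <- grepl("^[0-9]+$", surf)

    # sentence-initial: first token, or a '.', '!', '?' or newline in the
    # inter-token gap before this token.
    gap_from <- c(0L, tokens$end[-n])
    gaps <- substring(doc$text, gap_from + 1L, tokens$start)
    sentence_initial <- c(TRUE, grepl("[.!?\n]", gaps[-1]))

    known <- lower %in% names(tagmap)
    tags <- rep("NN", n)
    tags[known] <- unname(tagmap[lower[known]])
    # capitalised mid-sentence words override the lexicon: "John White"
    tags[capitalised & !sentence_initial] <- "NNP"
    # capitalised sentence-initial words unknown to the lexicon default NNP
    tags[capitalised & sentence_initial & !known] <- "NNP"
    tags[!capitalised & !known] <- "NN"
    tags[all_digit] <- "CD"
    tags
  }
}
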