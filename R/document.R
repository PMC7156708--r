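#' Note documents and token spans
#'
#' A `note_document` is an immutable plain-text clinical note together with
#' its identifier and character count.  All downstream stages address the
#' note through 0-based, half-open character intervals `[start, end)` so that
#' every labelling decision is traceable to exact positions in the original
#' text and the obfuscated output can be built with character-for-character
#' alignment.
#'
#' @param text Single character string, the raw note text.  Normalised to
#'   NFC on construction.
#' @param note_id Opaque note identifier (defaults to `"note"`).
#' @return An object of class `note_document` with fields `note_id`, `text`
#'   and `length` (number of characters).
#' @examples
#' doc <- note_document("Patient John White presents with pain.")
#' doc$length
#' @export
note_document <- function(text, note_id = "note") {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  stopifnot(is.character(note_id), length(note_id) == 1L)
  text <- enc2utf8(text)
  # NFC normalisation: clinical exports occasionally contain decomposed
  # accents; a stable composed form keeps offsets reproducible across OSes.
  if (requireNamespace("stringi", quietly = TRUE)) {
    text <- stringi::stri_trans_nfc(text)
  }
  structure(
    list(note_id = note_id, text = text, length = nchar(text, type = "chars")),
    class = "note_document"
  )
}

#' @export
print.note_document <- function(x, ...) {
  cat(sprintf("<note_document '%s': %d characters>\n", x$note_id, x$length))
  invisible(x)
}

#' Read a plain-text note from disk
#'
#' One note per UTF-8 `.txt` file; the note id is the file stem.
#'
#' @param path Path to a `.txt` file.
#' @return A [note_document].
#' @export
read_note <- function(path) {
  if (!file.exists(path)) stop("note file not found: ", path)
  raw <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  note_document(raw, note_id = tools::file_path_sans_ext(basename(path)))
}

# The token universe: maximal runs of letters/digits.  Everything else
# (whitespace, '-', '/', '#', '&', '.', ',', ':', ';', parens, quotes,
# apostrophes and any other non-alphanumeric character) is a separator.
.token_regex <- "[\\p{L}\\p{N}]+"

#' Tokenize a note into character-aligned spans
#'
#' Tokens are the maximal runs of alphanumeric characters; every other
#' character (whitespace and symbols such as `-`, `/`, `#`, `&`, periods,
#' commas, colons, quotes) is a separator.  Each token records its exact
#' 0-based half-open character interval, so replacing every surface at its
#' offsets reconstructs the original text byte for byte.
#'
#' @param doc A [note_document].
#' @return A data frame with one row per token and columns `start`, `end`
#'   (0-based, half-open), `surface`, `pos_tag` (initially `"UNSET"`),
#'   `label` (initially `"UNMARKED"`), `category` (initially `"NONE"`) and
#'   `stage` (initially `"NONE"`).  Rows are sorted by `start` and
#'   non-overlapping.
#' @examples
#' tokenize(note_document("Doe, Jane"))[, c("surface", "start", "end")]
#' @export
tokenize <- function(doc) {
  stopifnot(inherits(doc, "note_document"))
  if (doc$length == 0L) return(empty_tokens())
  m <- gregexpr(.token_regex, doc$text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_tokens())
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  tok <- data.frame(
    start = start1 - 1L,
    end = start1 - 1L + len,
    surface = substring(doc$text, start1, start1 + len - 1L),
    pos_tag = "UNSET",
    label = "UNMARKED",
    category = "NONE",
    stage = "NONE",
    stringsAsFactors = FALSE
  )
  tok
}

empty_tokens <- function() {
  data.frame(
    start = integer(0), end = integer(0), surface = character(0),
    pos_tag = character(0), label = character(0), category = character(0),
    stage = character(0), stringsAsFactors = FALSE
  )
}

#' Tokens adjacent to a position in the token stream
#'
#' Returns the up-to `2 * radius` tokens whose stream distance from the
#' token at `index` is at most `radius`, excluding `index` itself, in
#' document order.  Used by the name-context, initials and age stages,
#' whose conditions refer to "adjacent" tokens.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param index 1-based row index of the focal token.
#' @param radius Maximum stream distance (default 1).
#' @return Subset of `tokens` rows.
#' @export
adjacent_tokens <- function(tokens, index, radius = 1L) {
  n <- nrow(tokens)
  if (index < 1L || index > n) stop("token index out of range: ", index)
  if (radius < 1L) stop("radius must be >= 1")
  idx <- setdiff(seq(max(1L, index - radius), min(n, index + radius)), index)
  tokens[idx, , drop = FALSE]
}

#' Tokens intersecting a character interval
#'
#' Maps a raw-text match onto the token stream: every token whose interval
#' intersects `[start, end)` is returned, and a partial character overlap
#' includes the whole token (privacy-conservative projection).
#'
#' @param tokens Token data frame.
#' @param start,end 0-based half-open character interval.
#' @return Integer vector of row indices into `tokens`.
#' @export
span_to_tokens <- function(tokens, start, end) {
  if (start > end) stop("invalid span: start > end")
  if (start == end || nrow(tokens) == 0L) return(integer(0))
  which(tokens$start < end & tokens$end > start)
}

# Mark UNMARKED tokens at the given row indices; first-writer-wins is the
# global labelling rule, so already-labelled tokens are never touched.
mark_tokens <- function(tokens, idx, label, category = "NONE", stage) {
  idx <- idx[tokens$label[idx] == "UNMARKED"]
  if (length(idx)) {
    tokens$label[idx] <- label
    tokens$category[idx] <- category
    tokens$stage[idx] <- stage
  }
  tokens
}

#' Default PHI category registry
#'
#' The closed set of PHI category names used by detection stages, gold
#' readers and leakage reports.  The registry is initialised with the
#' patient/provider taxonomy used by hospital-style annotations and can be
#' extended at run time via [register_phi_category()] (unknown categories
#' in gold files are registered dynamically with a warning).
#'
#' @return Character vector of category names.
#' @export
phi_categories <- function() {
  get("categories", envir = .phifilter_registry)
}

.phifilter_registry <- new.env(parent = emptyenv())
assign("categories", c(
  "Age >= 90",
  "Patient_Vehicle_or_Device_Id",
  "Patient_Account_Number",
  "Patient_Medical_Record_Id",
  "Patient_Social_Security_Number",
  "Patient_Phone_Fax",
  "Patient_Initials",
  "Patient_Name_or_Family_Member_Name",
  "Patient_Address",
  "Patient_Unique_ID",
  "Email",
  "URL_IP",
  "Date",
  "Provider_Certificate_or_License",
  "Provider_Name",
  "Provider_Initials",
  "Provider_Address_or_Location",
  "Provider_Phone_Fax",
  "Name",
  "Initials"
), envir = .phifilter_registry)

#' @rdname phi_categories
#' @param name New category name to register.
#' @export
register_phi_category <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  cur <- phi_categories()
  if (!name %in% cur) {
    assign("categories", c(cur, name), envir = .phifilter_registry)
  }
  invisible(name)
}
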