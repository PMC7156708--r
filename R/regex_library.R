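#' Regular-expression libraries
#'
#' A regex library is an ordered table of patterns applied to the raw note
#' text.  Each entry carries a polarity — `SAFE` entries mark matched tokens
#' for inclusion, `PHI` entries mark them for exclusion — and PHI entries
#' carry the category assigned on exclusion.  Patterns may use lookaround
#' to express context conditions (for example a number adjacent to a
#' trigger word) directly over the raw text.
#'
#' @param entries Data frame with columns `pattern`, `polarity`
#'   (`"SAFE"`/`"PHI"`), `category` (a registered PHI category, or `"NONE"`
#'   for SAFE entries) and `description`.
#' @return An object of class `regex_library`.
#' @export
regex_library <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("pattern", "polarity", "category") %in% names(entries)))
  if (!"description" %in% names(entries)) {
    entries$description <- rep("", nrow(entries))
  }
  if (!all(entries$polarity %in% c("SAFE", "PHI"))) {
    stop("polarity must be SAFE or PHI")
  }
  bad_cat <- entries$polarity == "PHI" & entries$category == "NONE"
  if (any(bad_cat)) stop("every PHI entry needs a category")
  for (p in entries$pattern) {
    ok <- tryCatch({ regexpr(p, "", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("pattern does not compile: ", p)
  }
  structure(entries[, c("pattern", "polarity", "category", "description")],
            class = c("regex_library", "data.frame"))
}

#' Read a regex library from a TSV file
#'
#' Format: tab-separated with a header line
#' `pattern<TAB>polarity<TAB>category<TAB>description`; lines starting with
#' `#` are comments.  Shipped default libraries live under the package's
#' `extdata/` directory.
#'
#' @param path Path to the TSV file.
#' @return A [regex_library].
#' @export
read_regex_library <- function(path) {
  if (!file.exists(path)) stop("regex library not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  df <- utils::read.delim(text = lines, header = TRUE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  regex_library(df)
}

# All matches of one perl pattern on text, as a data.frame of 0-based
# half-open spans.  Empty matches are dropped.
match_spans <- function(pattern, text) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  len <- attr(m, "match.length")
  keep <- len > 0L
  data.frame(start = as.integer(m)[keep] - 1L,
             end = as.integer(m)[keep] - 1L + len[keep])
}
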