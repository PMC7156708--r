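#' Pipeline configuration
#'
#' The cascade is driven by a JSON configuration: an ordered `stages`
#' array (each stage has a unique `name`, a `kind` and a `params` table),
#' the obfuscation character, and the POS tagger identifier.  Stage order
#' is label priority: under first-writer-wins, earlier stages beat later
#' ones.  Resource references in `params` may be plain paths,
#' `"extdata:<file>"` for resources shipped with the package, or
#' `"build:last_names"` / `"build:first_names"` / `"build:whitelist"` for
#' lexicons built from the shipped fixture frequency tables.
#'
#' @param path Path to a JSON configuration file.
#' @return A list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_pipeline_config(cfg)
}

as_pipeline_config <- function(cfg) {
  if (is.null(cfg$obfuscation_char)) cfg$obfuscation_char <- "*"
  if (is.null(cfg$pos_tagger)) cfg$pos_tagger <- "rule"
  if (is.null(cfg$seed)) cfg$seed <- 0L
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

.stage_kinds <- c("safe_regex", "phi_regex", "age_rule", "pos_tag",
                  "name_blacklist", "name_context", "whitelist", "initials")
.tag_requiring <- c("name_blacklist", "whitelist")

#' Validate a pipeline configuration
#'
#' Checks stage kinds, name uniqueness, resource resolvability, that the
#' obfuscation character is a single character, and that a `pos_tag` stage
#' precedes every stage that needs POS tags.  Fails hard before any note
#' is processed.
#'
#' @param cfg A `pipeline_config` (or the path to one).
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (nchar(cfg$obfuscation_char) != 1L) {
    stop("obfuscation_char must be a single character")
  }
  stages <- cfg$stages
  if (is.null(stages) || !length(stages)) stop("config has no stages")
  names_ <- vapply(stages, function(s) s$name %||% "", "")
  kinds <- vapply(stages, function(s) s$kind %||% "", "")
  if (any(!nzchar(names_))) stop("every stage needs a name")
  if (anyDuplicated(names_)) stop("stage names must be unique")
  unknown <- setdiff(kinds, .stage_kinds)
  if (length(unknown)) stop("unknown stage kind(s): ",
                            paste(unknown, collapse = ", "))
  tag_pos <- match("pos_tag", kinds)
  needs <- which(kinds %in% .tag_requiring)
  if (length(needs) && (is.na(tag_pos) || any(needs < tag_pos))) {
    stop("a pos_tag stage must precede blacklist and whitelist stages")
  }
  for (s in stages) {
    for (key in c("library", "lexicon", "first_names", "last_names")) {
      ref <- s$params[[key]]
      if (!is.null(ref)) resolve_resource_path(ref)  # errors if unresolvable
    }
  }
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_resource_path <- function(ref) {
  if (startsWith(ref, "extdata:")) {
    path <- system.file("extdata", sub("^extdata:", "", ref),
                        package = "phifilter")
    if (!nzchar(path)) stop("shipped resource not found: ", ref)
    return(path)
  }
  if (startsWith(ref, "build:")) {
    if (!sub("^build:", "", ref) %in%
          c("last_names", "first_names", "whitelist")) {
      stop("unknown build resource: ", ref)
    }
    return(ref)
  }
  if (!file.exists(ref)) stop("resource not found: ", ref)
  ref
}

#' Default pipeline configuration
#'
#' Reproduces the published stage order: safe patterns, PHI patterns, the
#' age rule, POS tagging, the last-name blacklist, the first-name
#' blacklist, name-context patterns, the whitelist safety net, and the
#' initials detector, followed by final disposition.  Resources are the
#' fixture lexicon sources and curated pattern libraries shipped with the
#' package.
#'
#' @return A `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  read_pipeline_config(system.file("extdata", "default_config.json",
                                   package = "phifilter"))
}

# Build the default fixture lexicons (memoised per session).
.lexicon_cache <- new.env(parent = emptyenv())

built_lexicon <- function(which) {
  key <- which
  if (!is.null(.lexicon_cache[[key]])) return(.lexicon_cache[[key]])
  extdata <- function(f) system.file("extdata", f, package = "phifilter")
  excl <- readLines(extdata("exclusion_words.txt"), warn = FALSE)
  excl <- tolower(excl[nzchar(excl) & !startsWith(excl, "#")])
  cfg <- blacklist_build_config(exclusion_words = excl)
  lex <- switch(
    which,
    last_names = build_last_name_blacklist(
      utils::read.delim(extdata("census_surnames_synthetic.tsv"),
                        stringsAsFactors = FALSE), cfg),
    first_names = build_first_name_blacklist(
      utils::read.delim(extdata("ssa_firstnames_synthetic.tsv"),
                        stringsAsFactors = FALSE), cfg),
    whitelist = {
      vocab <- lapply(c("english_words.txt", "medical_terms.txt"),
                      function(f) readLines(extdata(f), warn = FALSE))
      add_back <- readLines(extdata("add_back_words.txt"), warn = FALSE)
      add_back <- tolower(add_back[nzchar(add_back) &
                                     !startsWith(add_back, "#")])
      build_whitelist(vocab,
                      list(built_lexicon("last_names"),
                           built_lexicon("first_names")),
                      add_back = c(excl, add_back))
    },
    stop("unknown built lexicon: ", which)
  )
  .lexicon_cache[[key]] <- lex
  lex
}

resolve_lexicon <- function(ref) {
  if (startsWith(ref, "build:")) return(built_lexicon(sub("^build:", "", ref)))
  load_lexicon(resolve_resource_path(ref))
}

resolve_library <- function(ref) {
  read_regex_library(resolve_resource_path(ref))
}

# Compile a config into a list of stage closures over (doc, tokens).
compile_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  tagger <- rule_tagger()
  lapply(cfg$stages, function(s) {
    p <- s$params %||% list()
    fn <- switch(
      s$kind,
      safe_regex = {
        lib <- resolve_library(p$library)
        function(doc, tokens) apply_safe_regex(doc, tokens, lib, s$name)
      },
      phi_regex = {
        lib <- resolve_library(p$library)
        function(doc, tokens) apply_phi_regex(doc, tokens, lib, s$name)
      },
      age_rule = {
        acfg <- age_rule_config(
          trigger_words = unlist(p$trigger_words) %||%
            c("age", "years old", "y.o."),
          threshold = p$threshold %||% 90L,
          context_radius = p$context_radius %||% 2L)
        function(doc, tokens) apply_age_rule(doc, tokens, acfg, s$name)
      },
      pos_tag = function(doc, tokens) pos_tag(doc, tokens, tagger),
      name_blacklist = {
        first <- if (!is.null(p$first_names)) resolve_lexicon(p$first_names)
        last <- if (!is.null(p$last_names)) resolve_lexicon(p$last_names)
        if (is.null(first) && is.null(last) && !is.null(p$lexicon)) {
          last <- resolve_lexicon(p$lexicon)
        }
        function(doc, tokens) {
          apply_name_blacklist(tokens, first, last, s$name)
        }
      },
      name_context = {
        lib <- resolve_library(p$library)
        function(doc, tokens) {
          apply_name_context(doc, tokens, lib, stage = s$name)
        }
      },
      whitelist = {
        lex <- resolve_lexicon(p$lexicon)
        function(doc, tokens) apply_whitelist(tokens, lex, stage = s$name)
      },
      initials = {
        lib <- resolve_library(p$library)
        function(doc, tokens) {
          apply_initials(doc, tokens, lib, stage = s$name)
        }
      }
    )
    list(name = s$name, kind = s$kind, fn = fn)
  })
}

#' De-identify a single note
#'
#' Runs the configured stages in order under first-writer-wins, then
#' applies final disposition: tokens marked for inclusion are retained
#' verbatim; tokens marked for exclusion *and tokens never labelled by any
#' stage* are obfuscated.  Retaining only what some stage affirmatively
#' marked safe is the privacy-conservative disposition.
#'
#' @param doc A [note_document].
#' @param cfg A `pipeline_config` (default: the shipped configuration).
#' @param compiled Optional pre-compiled pipeline from the same config
#'   (an optimisation for corpus runs); if supplied, `cfg` is only used
#'   for the obfuscation character.
#' @return A list of class `deid_result` with fields `note_id`,
#'   `output_text` (same character count as the input), `tokens` (final
#'   labelled spans) and `stage_log` (labels assigned per stage).
#' @examples
#' \donttest{
#' res <- run_note(note_document("Patient John White presents with pain."))
#' res$output_text
#' }
#' @export
run_note <- function(doc, cfg = default_pipeline_config(), compiled = NULL) {
  if (is.null(compiled)) compiled <- compile_pipeline(cfg)
  tokens <- tokenize(doc)
  stage_log <- list()
  for (st in compiled) {
    before <- tokens$label
    tokens <- st$fn(doc, tokens)
    after <- tokens$label
    changed <- before != after
    if (any(before != "UNMARKED" & changed)) {
      stop("stage '", st$name, "' overwrote an existing label")
    }
    stage_log[[st$name]] <- c(
      include = sum(after[changed] == "INCLUDE"),
      exclude = sum(after[changed] == "EXCLUDE")
    )
  }
  out <- obfuscate(doc, tokens, obfuscation_char = cfg$obfuscation_char)
  structure(list(note_id = doc$note_id, output_text = out,
                 tokens = tokens, stage_log = stage_log),
            class = "deid_result")
}

#' @export
print.deid_result <- function(x, ...) {
  lab <- table(factor(x$tokens$label,
                      levels = c("INCLUDE", "EXCLUDE", "UNMARKED")))
  cat(sprintf(
    "<deid_result '%s': %d tokens (%d include, %d exclude, %d unmarked)>\n",
    x$note_id, nrow(x$tokens), lab["INCLUDE"], lab["EXCLUDE"],
    lab["UNMARKED"]))
  invisible(x)
}

#' Character-aligned obfuscation
#'
#' Every character of every token not marked for inclusion is replaced by
#' the obfuscation character ("John Smith" becomes "**** *****");
#' separators between and around tokens are preserved in place, so the
#' output has exactly the character count and structure of the input.  Any
#' obfuscation character already present in the original text is replaced
#' by a space, so that an asterisk in the output always and only means
#' "removed".
#'
#' @param doc A [note_document].
#' @param final_tokens Token data frame after all stages.
#' @param obfuscation_char Single replacement character (default `"*"`).
#' @return The obfuscated text, same character count as `doc$text`.
#' @export
obfuscate <- function(doc, final_tokens, obfuscation_char = "*") {
  stopifnot(nchar(obfuscation_char) == 1L)
  if (doc$length == 0L) return("")
  chars <- strsplit(doc$text, "", fixed = TRUE)[[1]]
  chars[chars == obfuscation_char] <- " "
  drop <- final_tokens$label != "INCLUDE"
  for (i in which(drop)) {
    chars[(final_tokens$start[i] + 1L):final_tokens$end[i]] <-
      obfuscation_char
  }
  paste(chars, collapse = "")
}

#' De-identify a directory of notes
#'
#' Processes every `.txt` note in `input_dir` independently (output does
#' not depend on processing order), writes one same-named output note per
#' input to `output_dir`, and writes a JSON run manifest with per-note
#' stage logs.  Unreadable files are skipped and recorded in the manifest.
#' Stage logs count labels only; token surfaces of excluded tokens are
#' never written to the manifest (they are PHI).
#'
#' @param input_dir Directory of UTF-8 `.txt` notes.
#' @param output_dir Output directory (created if needed).
#' @param cfg A `pipeline_config`.
#' @return Invisibly, the manifest list (also written to
#'   `output_dir/manifest.json`).
#' @export
run_corpus <- function(input_dir, output_dir,
                       cfg = default_pipeline_config()) {
  files <- sort(list.files(input_dir, pattern = "\\.txt$",
                           full.names = TRUE))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  compiled <- compile_pipeline(cfg)
  notes <- list()
  skipped <- character(0)
  for (f in files) {
    res <- tryCatch({
      doc <- read_note(f)
      r <- run_note(doc, cfg, compiled = compiled)
      out_path <- file.path(output_dir, basename(f))
      writeLines(r$output_text, out_path, sep = "", useBytes = TRUE)
      notes[[r$note_id]] <- list(
        n_tokens = nrow(r$tokens),
        labels = as.list(table(r$tokens$label)),
        stage_log = r$stage_log)
      TRUE
    }, error = function(e) {
      skipped <<- c(skipped, basename(f))
      FALSE
    })
  }
  manifest <- list(n_notes = length(notes), skipped = skipped, notes = notes)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
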