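#' Synthetic annotated-note generation
#'
#' Seeded generator of clinical-flavoured notes with exact gold PHI
#' character spans, covering the full PHI taxonomy (patient and provider
#' names, initials, dates, ages at or above 90, phone/fax numbers, SSNs,
#' addresses, emails, URLs/IPs, record/account/device identifiers,
#' certificates).  It exists so that every cascade stage and the evaluator
#' can be developed and tested without access to any protected corpus:
#' templates plus realizers emulate the *failure modes* that matter
#' (name/common-word ambiguity, misspelled names, varied date and number
#' formats), not the statistics of real clinical language.
#'
#' @param seed Integer seed driving all randomness (one global seed, no
#'   hidden entropy sources).
#' @param n_notes Number of notes to generate.
#' @param category_mix Named numeric vector: expected PHI instances per
#'   note for each category.  Defaults cover the whole taxonomy.
#' @param ambiguous_fraction Fraction of surnames drawn from the pool of
#'   names that are also common English words (e.g. "White", "Young") —
#'   the cases the POS gate exists for.
#' @param misspelling_rate Fraction of name instances with one character
#'   mutated, emulating out-of-lexicon names.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_notes = 10L, category_mix = NULL,
                         ambiguous_fraction = 0.2, misspelling_rate = 0.05) {
  if (is.null(category_mix)) category_mix <- default_category_mix()
  stopifnot(all(category_mix >= 0), !is.null(names(category_mix)),
            ambiguous_fraction >= 0, ambiguous_fraction <= 1,
            misspelling_rate >= 0, misspelling_rate <= 1)
  structure(list(seed = as.integer(seed), n_notes = as.integer(n_notes),
                 category_mix = category_mix,
                 ambiguous_fraction = ambiguous_fraction,
                 misspelling_rate = misspelling_rate),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_category_mix <- function() {
  c("Patient_Name_or_Family_Member_Name" = 1.5,
    "Provider_Name" = 0.8,
    "Date" = 2.0,
    "Age >= 90" = 0.3,
    "Patient_Phone_Fax" = 0.4,
    "Provider_Phone_Fax" = 0.2,
    "Patient_Social_Security_Number" = 0.2,
    "Patient_Address" = 0.3,
    "Provider_Address_or_Location" = 0.2,
    "Email" = 0.3,
    "URL_IP" = 0.3,
    "Patient_Unique_ID" = 0.4,
    "Patient_Medical_Record_Id" = 0.3,
    "Patient_Account_Number" = 0.2,
    "Patient_Vehicle_or_Device_Id" = 0.1,
    "Patient_Initials" = 0.3,
    "Provider_Initials" = 0.3,
    "Provider_Certificate_or_License" = 0.1)
}

# Name pools.  All surnames/first names below the "ambiguous" pool also
# appear in the shipped fixture frequency tables above threshold, so the
# default blacklists cover the generator's name pool.
.synth_pools <- function() {
  list(
    first = c("James", "Maria", "Robert", "Elena", "Michael", "Aisha",
              "David", "Susan", "Carlos", "Linda", "Ahmed", "Grace",
              "Thomas", "Priya", "Daniel", "Rosa", "Kevin", "Anna",
              "Jane", "John"),
    last = c("Smith", "Johnson", "Williams", "Garcia", "Martinez",
             "Nguyen", "Patel", "Kim", "Hernandez", "Lopez", "Chen",
             "Washington", "Okafor", "Doe", "Brown", "Davis"),
    # surnames that are also common English words: the POS-gate stress set
    ambiguous = c("White", "Young", "Price", "Bell", "Berry", "Stone"),
    street = c("Maple", "Oak", "Cedar", "Hill", "Lake", "Park"),
    facility = c("Bayview Medical Center", "Lakeside Clinic",
                 "Hillcrest Hospital", "Northgate Health Pavilion"),
    domain = c("example.org", "mailhost.net", "clinicmail.com")
  )
}

.safe_templates <- c(
  "The patient presents with chest pain and shortness of breath.",
  "Blood pressure stable, heart rate regular, lungs clear to auscultation.",
  "Started aspirin 81 mg daily and metformin 500 mg twice daily.",
  "White fluid found at the wound site, culture sent to the lab.",
  "Follow up in clinic after labs, continue current medications.",
  "No fever, no chills, denies nausea and vomiting.",
  "Physical exam unremarkable, abdomen soft and nontender.",
  "Assessment and plan discussed, patient verbalized understanding.",
  "Renal function within normal limits, potassium stable.",
  "Imaging reviewed, no acute findings on the chest radiograph."
)

.phi_templates <- list(
  "Patient_Name_or_Family_Member_Name" = c(
    "The patient {PHI} returned to clinic for follow up.",
    "Plan was discussed with {PHI} at the bedside.",
    "Patient {PHI} presents with worsening joint pain."),
  "Provider_Name" = c(
    "Seen by Dr. {PHI} in the rheumatology clinic.",
    "Care transferred to Dr. {PHI} for ongoing management."),
  "Date" = c(
    "Last seen in clinic on {PHI} for routine review.",
    "Symptoms began around {PHI} per the patient.",
    "Next appointment scheduled for {PHI}."),
  "Age >= 90" = c(
    "The patient is {PHI} years old and lives independently.",
    "Notable for age {PHI} with intact cognition."),
  "Patient_Phone_Fax" = c(
    "Patient can be reached at {PHI} for scheduling.",
    "Left a message at {PHI} regarding lab results."),
  "Provider_Phone_Fax" = c(
    "Clinic fax {PHI} for records requests.",
    "Page the covering physician at {PHI} overnight."),
  "Patient_Social_Security_Number" = c(
    "SSN {PHI} verified at registration."),
  "Patient_Address" = c(
    "The patient lives at {PHI} with family.",
    "Discharge to home address {PHI} arranged."),
  "Provider_Address_or_Location" = c(
    "Clinic located at {PHI} for in person visits.",
    "Transferred from {PHI} earlier today."),
  "Email" = c(
    "Results sent to {PHI} as requested.",
    "Patient prefers contact by email at {PHI}."),
  "URL_IP" = c(
    "Imaging available at {PHI} for review.",
    "Portal access logged from {PHI} yesterday."),
  "Patient_Unique_ID" = c(
    "Unique identifier {PHI} confirmed in the chart."),
  "Patient_Medical_Record_Id" = c(
    "MRN {PHI} verified against the wristband."),
  "Patient_Account_Number" = c(
    "Billing account {PHI} updated after the visit."),
  "Patient_Vehicle_or_Device_Id" = c(
    "Pacemaker serial {PHI} interrogated, battery adequate."),
  "Patient_Initials" = c(
    "Consent signed by {PHI} in the presence of staff."),
  "Provider_Initials" = c(
    "Countersigned by {PHI} attending of record."),
  "Provider_Certificate_or_License" = c(
    "Covering provider license {PHI} on file.")
)

# Realize one PHI surface for a category.  Returns a single string; the
# entire string is PHI (context words live in the templates).
realize_phi <- function(category, pools, cfg) {
  pick <- function(x) x[sample.int(length(x), 1L)]
  misspell <- function(w) {
    if (stats::runif(1) >= cfg$misspelling_rate || nchar(w) < 4L) return(w)
    i <- sample(2:(nchar(w) - 1L), 1L)
    substr(w, i, i) <- pick(letters)
    w
  }
  surname <- function() {
    if (stats::runif(1) < cfg$ambiguous_fraction) pick(pools$ambiguous)
    else pick(pools$last)
  }
  name_pair <- function() paste(misspell(pick(pools$first)),
                                misspell(surname()))
  initials <- function() {
    paste0(surname(), ", ", substr(pick(pools$first), 1L, 1L), ".")
  }
  digits <- function(n) {
    paste(sample(0:9, n, replace = TRUE), collapse = "")
  }
  switch(
    category,
    "Patient_Name_or_Family_Member_Name" = name_pair(),
    "Provider_Name" = name_pair(),
    "Date" = {
      y <- sample(1998:2019, 1L); m <- sample(1:12, 1L)
      d <- sample(1:28, 1L)
      fmt <- sample(1:4, 1L)
      months <- c("January", "February", "March", "April", "May", "June",
                  "July", "August", "September", "October", "November",
                  "December")
      switch(fmt,
             sprintf("%02d/%02d/%d", m, d, y),
             sprintf("%d-%02d-%02d", y, m, d),
             sprintf("%s %d, %d", months[m], d, y),
             sprintf("%d %s %d", d, months[m], y))
    },
    "Age >= 90" = as.character(sample(90:103, 1L)),
    "Patient_Phone_Fax" = sprintf("(%d) %d-%s", sample(201:989, 1L),
                                  sample(200:999, 1L), digits(4L)),
    "Provider_Phone_Fax" = sprintf("%d-%d-%s", sample(201:989, 1L),
                                   sample(200:999, 1L), digits(4L)),
    "Patient_Social_Security_Number" = sprintf("%s-%s-%s", digits(3L),
                                               digits(2L), digits(4L)),
    "Patient_Address" = sprintf("%d %s Street", sample(10:9999, 1L),
                                pick(pools$street)),
    "Provider_Address_or_Location" = pick(pools$facility),
    "Email" = paste0(tolower(pick(pools$first)), sample(10:99, 1L), "@",
                     pick(pools$domain)),
    "URL_IP" = if (stats::runif(1) < 0.5) {
      paste0("https://portal.", pick(pools$domain), "/chart")
    } else {
      paste(sample(1:254, 4L, replace = TRUE), collapse = ".")
    },
    "Patient_Unique_ID" = digits(8L),
    "Patient_Medical_Record_Id" = digits(8L),
    "Patient_Account_Number" = digits(9L),
    "Patient_Vehicle_or_Device_Id" = paste0("PM", digits(7L)),
    "Patient_Initials" = initials(),
    "Provider_Initials" = initials(),
    "Provider_Certificate_or_License" = paste0("G", digits(6L)),
    stop("no realizer for category: ", category)
  )
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the seed: two runs with the same configuration
#' produce byte-identical corpora.  Per-category instance counts follow a
#' binomial draw per note with the configured expectation; gold offsets
#' exactly locate every injected PHI surface, and nothing outside the
#' gold spans is PHI by construction.
#'
#' @param cfg A [synth_config].
#' @return A list of `synth_note` objects, each with fields `doc`
#'   ([note_document]) and `gold` ([gold_annotation], MAE dialect).
#' @export
generate_corpus <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!length(.safe_templates) || !length(.phi_templates)) {
    stop("empty templates")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed, kind = "Mersenne-Twister")
  pools <- .synth_pools()
  max_draw <- 8L  # binomial size per note/category; mean = category_mix
  lapply(seq_len(cfg$n_notes), function(i) {
    sentences <- character(0)
    phi <- data.frame(sentence = integer(0), surface = character(0),
                      category = character(0), stringsAsFactors = FALSE)
    # safe filler sentences
    n_safe <- sample(3:6, 1L)
    sentences <- sample(.safe_templates, n_safe, replace = TRUE)
    # PHI-bearing sentences
    for (category in names(cfg$category_mix)) {
      mix <- cfg$category_mix[[category]]
      if (mix <= 0) next
      count <- stats::rbinom(1L, max_draw, min(1, mix / max_draw))
      for (k in seq_len(count)) {
        tmpl <- .phi_templates[[category]]
        if (is.null(tmpl)) stop("no template for category: ", category)
        tmpl <- tmpl[sample.int(length(tmpl), 1L)]
        surface <- realize_phi(category, pools, cfg)
        sentences <- c(sentences,
                       sub("{PHI}", surface, tmpl, fixed = TRUE))
        phi <- rbind(phi, data.frame(
          sentence = length(sentences), surface = surface,
          category = category, stringsAsFactors = FALSE))
      }
    }
    # shuffle sentence order, tracking where each PHI sentence lands
    ord <- sample.int(length(sentences))
    sentences <- sentences[ord]
    phi$sentence <- match(phi$sentence, ord)
    # assemble text and compute exact character offsets
    text <- paste(sentences, collapse = " ")
    sent_start <- cumsum(c(0L, nchar(sentences) + 1L))  # 0-based
    spans <- data.frame(start = integer(0), end = integer(0),
                        category = character(0), surface = character(0),
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(phi))) {
      s_idx <- phi$sentence[r]
      tmpl_sentence <- sentences[s_idx]
      rel <- regexpr(phi$surface[r], tmpl_sentence, fixed = TRUE)
      stopifnot(rel > 0)
      start <- sent_start[s_idx] + as.integer(rel) - 1L
      spans <- rbind(spans, data.frame(
        start = start, end = start + nchar(phi$surface[r]),
        category = phi$category[r], surface = phi$surface[r],
        stringsAsFactors = FALSE))
    }
    note_id <- sprintf("synthnote_%04d", i)
    doc <- note_document(text, note_id)
    structure(list(doc = doc,
                   gold = gold_annotation(note_id, spans, "mae")),
              class = "synth_note")
  })
}

#' Perfect-knowledge reference filter
#'
#' Obfuscates exactly the gold spans of a synthetic note using the
#' pipeline's [obfuscate()] operation.  It is the upper-bound reference
#' for the evaluator: by construction, evaluating its output against the
#' note's own gold yields recall = precision = 100.
#'
#' @param note A `synth_note`.
#' @param obfuscation_char Obfuscation character (default `"*"`).
#' @return The de-identified text, character-aligned with the input.
#' @export
oracle_filter <- function(note, obfuscation_char = "*") {
  stopifnot(inherits(note, "synth_note"))
  tokens <- tokenize(note$doc)
  tokens$label <- "INCLUDE"
  for (i in seq_len(nrow(note$gold$spans))) {
    idx <- span_to_tokens(tokens, note$gold$spans$start[i],
                          note$gold$spans$end[i])
    tokens$label[idx] <- "EXCLUDE"
  }
  obfuscate(note$doc, tokens, obfuscation_char)
}

#' Write a synthetic corpus to disk
#'
#' Produces `notes/<id>.txt` (UTF-8 plain text) and `gold/<id>.xml`
#' (MAE-style dialect, so the standard gold reader path applies).
#'
#' @param notes List of `synth_note` objects from [generate_corpus()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_synth_corpus <- function(notes, out_dir) {
  notes_dir <- file.path(out_dir, "notes")
  gold_dir <- file.path(out_dir, "gold")
  for (d in c(notes_dir, gold_dir)) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  for (nt in notes) {
    writeLines(nt$doc$text, file.path(notes_dir,
                                      paste0(nt$doc$note_id, ".txt")),
               sep = "", useBytes = TRUE)
    write_gold_mae(nt$gold, nt$doc$text,
                   file.path(gold_dir, paste0(nt$doc$note_id, ".xml")))
  }
  invisible(out_dir)
}
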