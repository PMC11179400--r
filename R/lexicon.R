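#' Complication term lexicon
#'
#' The lexicon drives [find_mentions()]: an ordered list of complication
#' search phrases plus the negation machinery (pre- and post-position cues,
#' scope terminators and a token window). Phrases are matched at word
#' boundaries, longest phrase first, on normalized text.
#'
#' @param complication_terms character vector of lowercase search phrases.
#' @param negation_cues_pre cues that negate a term when they appear within
#'   `window_tokens` tokens *before* it with no scope terminator between.
#' @param negation_cues_post cues that negate when they appear within
#'   `window_tokens` tokens *after* the term.
#' @param scope_terminators tokens that end a negation scope (adversative
#'   conjunctions and sentence punctuation).
#' @param window_tokens size of the negation window, in tokens.
#' @return an object of class `term_lexicon`.
#' @export
term_lexicon <- function(complication_terms,
                         negation_cues_pre = default_negation_cues()$pre,
                         negation_cues_post = default_negation_cues()$post,
                         scope_terminators = default_scope_terminators(),
                         window_tokens = 5L) {
  terms <- tolower(trimws(complication_terms))
  if (length(terms) == 0L) stop("complication_terms must be non-empty", call. = FALSE)
  if (anyDuplicated(terms)) stop("complication_terms contains duplicates", call. = FALSE)
  structure(list(complication_terms = terms,
                 negation_cues_pre = tolower(negation_cues_pre),
                 negation_cues_post = tolower(negation_cues_post),
                 scope_terminators = tolower(scope_terminators),
                 window_tokens = as.integer(window_tokens)),
            class = "term_lexicon")
}

default_negation_cues <- function() {
  list(pre = c("no", "not", "without", "denies", "denied",
               "negative for", "free of", "absent", "(-)"),
       post = c("was not seen", "were not seen", "not noted", "ruled out"))
}

default_scope_terminators <- function() {
  c("but", "however", "although", "though", "yet", ".", ";", ":")
}

#' Default complication term lexicon
#'
#' The twelve surgeon-derived complication search phrases used for
#' free-text review of operative reports and clinical notes, with
#' NegEx-convention negation defaults (window of 5 tokens; cues such as
#' "no", "without", "negative for"; scope ended by adversative conjunctions
#' and sentence punctuation).
#'
#' @return a [term_lexicon()].
#' @examples
#' default_term_lexicon()$complication_terms
#' @export
default_term_lexicon <- function() {
  term_lexicon(c("lens touch", "iris touch", "cornea touch", "bleeding",
                 "hemorrhage", "hyphema", "tear", "leak", "shallow",
                 "movement", "suprachoroidal", "endophthalmitis"))
}

#' Default anesthesia term lexicon
#'
#' The seven anesthesia search tokens matched (negation off) against the
#' anesthesia section of each operative report.
#'
#' @return character vector of lowercase search tokens.
#' @export
default_anesthesia_lexicon <- function() {
  c("topical", "intracameral", "subtenon", "peribulbar", "retrobulbar",
    "lidocaine", "general")
}

#' Read a term lexicon from a YAML or JSON config file
#'
#' The file may supply any subset of the [term_lexicon()] fields; omitted
#' fields take the packaged defaults. The packaged default config is at
#' `system.file("extdata", "lexicon.yaml", package = "aqsafe")`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [term_lexicon()].
#' @export
read_lexicon <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  d <- default_term_lexicon()
  pick <- function(nm) if (!is.null(raw[[nm]])) unlist(raw[[nm]]) else d[[nm]]
  term_lexicon(complication_terms = pick("complication_terms"),
               negation_cues_pre = pick("negation_cues_pre"),
               negation_cues_post = pick("negation_cues_post"),
               scope_terminators = pick("scope_terminators"),
               window_tokens = pick("window_tokens"))
}

#' @export
print.term_lexicon <- function(x, ...) {
  cat(sprintf("<term_lexicon> %d terms, window %d tokens\n",
              length(x$complication_terms), x$window_tokens))
  cat("  terms:", paste(x$complication_terms, collapse = ", "), "\n")
  invisible(x)
}
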