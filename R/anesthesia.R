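#' Extract the anesthesia section of an operative report
#'
#' Returns the report's anesthesia-section text when present and non-empty,
#' otherwise `NA`. An absent section triggers the no-hit review path in
#' [classify_anesthesia()]: recovering the anesthesia type from elsewhere in
#' the report body is a manual-review action, not an automated one.
#'
#' @param report a single document row (list or one-row data.frame) with
#'   `kind == "operative_report"`.
#' @return a string, or `NA_character_` when the section is absent/empty.
#' @export
extract_anesthesia_text <- function(report) {
  stopifnot(report[["kind"]] == "operative_report")
  txt <- report[["anesthesia_text"]]
  if (is.null(txt) || length(txt) == 0L || is.na(txt) || !nzchar(trimws(txt))) {
    return(NA_character_)
  }
  as.character(txt)
}

.local_labels <- c("retrobulbar", "peribulbar", "subtenon", "topical")

#' Classify the anesthesia type from the anesthesia-section text
#'
#' Runs the word-boundary term search (negation off) over the anesthesia
#' text and applies a fixed rule table:
#' a matched block term wins by depth (`retrobulbar` > `peribulbar` >
#' `subtenon` > `topical`, with `intracameral`/`lidocaine` treated as
#' topical adjuncts); `lidocaine` or `intracameral` alone cannot decide a
#' label and is referred to review; no matched term is a *no-hit* (label
#' `unknown`, review required); and a matched `general` is inspected for
#' documented misuse -- "general" within 3 tokens after "transient", or
#' co-occurrence with intravenous-sedation phrasing plus a local term -- in
#' which case the accompanying local term supplies the label and the case
#' is referred to review, otherwise the label is `general`.
#'
#' @param call_text anesthesia-section text, or `NA` (see
#'   [extract_anesthesia_text()]).
#' @param body operative report body; carried for the reviewer, not used by
#'   the automated rules.
#' @param lexicon character vector of anesthesia search tokens,
#'   see [default_anesthesia_lexicon()].
#' @return one-row data.frame: `matched_terms` (`;`-joined), `auto_label`,
#'   `akinesia` (label implies ocular muscle akinesia), `no_hit`,
#'   `needs_review`, `review_reason`.
#' @examples
#' classify_anesthesia("topical anesthesia with intracameral lidocaine")
#' classify_anesthesia("monitored anesthesia care")
#' @export
classify_anesthesia <- function(call_text, body = "",
                                lexicon = default_anesthesia_lexicon()) {
  matched <- character(0)
  if (!is.na(call_text) && nzchar(trimws(call_text))) {
    txt <- normalize_text(call_text)
    matched <- lexicon[vapply(lexicon, function(t) {
      grepl(paste0("\\b", escape_regex(t), "\\b"), txt, perl = TRUE)
    }, logical(1))]
  }
  label <- "unknown"
  no_hit <- FALSE
  review <- FALSE
  reason <- "none"
  if (length(matched) == 0L) {
    no_hit <- TRUE
    review <- TRUE
    reason <- "no_hit"
  } else if ("general" %in% matched) {
    txt <- normalize_text(call_text)
    local_hit <- .local_labels[.local_labels %in% matched]
    if (general_misuse_pattern(txt, has_local = length(local_hit) > 0L)) {
      review <- TRUE
      reason <- "general_ambiguous"
      label <- if (length(local_hit)) local_hit[1] else "unknown"
    } else {
      label <- "general"
    }
  } else {
    local_hit <- .local_labels[.local_labels %in% matched]
    if (length(local_hit)) {
      label <- local_hit[1]                 # deepest block outranks topical
    } else {
      # lidocaine / intracameral alone: adjuncts, not a standalone label
      review <- TRUE
      reason <- "conflicting_terms"
    }
  }
  data.frame(matched_terms = paste(matched, collapse = ";"),
             auto_label = label,
             akinesia = label %in% c("retrobulbar", "general"),
             no_hit = no_hit,
             needs_review = review,
             review_reason = reason,
             stringsAsFactors = FALSE)
}

# "general" misuse: transient-general phrasing, or IV-sedation phrasing
# co-occurring with a local anesthesia term
general_misuse_pattern <- function(txt, has_local) {
  tok <- tokenize_offsets(txt)$token
  gpos <- which(tok == "general")
  tpos <- which(tok == "transient")
  transient_general <- any(vapply(gpos, function(g) {
    any(tpos < g & tpos >= g - 3L)
  }, logical(1)))
  sedation <- grepl("\\b(intravenous sedation|iv sedation|mac)\\b", txt,
                    perl = TRUE)
  transient_general || (sedation && has_local)
}

#' Classify anesthesia for every case of a corpus
#'
#' @param manifest manifest data.frame.
#' @param docs document data.frame; each case's operative report supplies
#'   the anesthesia section.
#' @param lexicon anesthesia token lexicon.
#' @return data.frame with one row per manifest case: `case_id` plus the
#'   [classify_anesthesia()] columns.
#' @export
classify_corpus_anesthesia <- function(manifest, docs,
                                       lexicon = default_anesthesia_lexicon()) {
  ops <- docs[docs$kind == "operative_report", , drop = FALSE]
  idx <- match(manifest$case_id, ops$case_id)
  if (anyNA(idx)) {
    stop(sprintf("no operative report for case(s): %s",
                 paste(manifest$case_id[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  calls <- lapply(seq_along(idx), function(i) {
    r <- ops[idx[i], , drop = FALSE]
    classify_anesthesia(extract_anesthesia_text(r), r$body, lexicon)
  })
  out <- do.call(rbind, calls)
  out <- cbind(case_id = manifest$case_id, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize anesthesia calls, applying review resolutions
#'
#' Review resolutions supply the final label for cases flagged
#' `needs_review` or `no_hit` (in synthetic runs they come from the planted
#' ground truth, standing in for the study's manual verification); all other
#' cases keep their automatic label. Reports both accuracy readings for the
#' automatic classifier: `auto_accuracy` scores every case by its automatic
#' label (no-hit cases count as errors), and `auto_accuracy_strict`
#' additionally counts every review-flagged case as requiring manual work.
#'
#' @param calls output of [classify_corpus_anesthesia()].
#' @param resolutions optional data.frame `case_id`, `final_label`.
#' @return list with `n`, `label_counts` (final labels), `n_no_hit`,
#'   `no_hit_fraction`, `n_general_term`, `n_general_resolved_local`,
#'   `auto_accuracy`, `auto_accuracy_strict`, `auto_accuracy_non_review`
#'   (accuracy among cases not flagged for review), `akinesia_count`,
#'   `akinesia_fraction`, and the per-case table `cases` with `final_label`.
#' @export
summarize_anesthesia <- function(calls, resolutions = NULL) {
  if (anyDuplicated(calls$case_id)) {
    stop("duplicate case_id in anesthesia calls", call. = FALSE)
  }
  final <- calls$auto_label
  if (!is.null(resolutions)) {
    if (anyDuplicated(resolutions$case_id)) {
      stop("duplicate case_id in resolutions", call. = FALSE)
    }
    idx <- match(calls$case_id, resolutions$case_id)
    has <- !is.na(idx)
    final[has] <- resolutions$final_label[idx[has]]
  }
  n <- nrow(calls)
  matched_general <- grepl("(^|;)general(;|$)", calls$matched_terms)
  correct <- calls$auto_label == final
  review <- calls$needs_review | calls$no_hit
  cases <- cbind(calls, final_label = final, stringsAsFactors = FALSE)
  list(n = n,
       label_counts = table(factor(final, levels = c(.local_labels, "general",
                                                     "unknown"))),
       n_no_hit = sum(calls$no_hit),
       no_hit_fraction = sum(calls$no_hit) / n,
       n_general_term = sum(matched_general),
       n_general_resolved_local = sum(matched_general &
                                        final %in% .local_labels),
       auto_accuracy = mean(correct),
       auto_accuracy_strict = mean(correct & !review),
       auto_accuracy_non_review = if (any(!review)) mean(correct[!review]) else NA_real_,
       akinesia_count = sum(final %in% c("retrobulbar", "general")),
       akinesia_fraction = sum(final %in% c("retrobulbar", "general")) / n,
       cases = cases)
}
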