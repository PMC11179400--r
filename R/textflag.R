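#' Normalize clinical free text
#'
#' Lowercases, maps Unicode quotes and dashes to their ASCII equivalents,
#' collapses runs of whitespace to single spaces and trims. All mention
#' spans produced by [find_mentions()] are 0-based, half-open offsets into
#' this normalized form.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @examples
#' normalize_text("No Lens  Touch")
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  # curly quotes, dashes, nbsp -> ascii
  x <- gsub("[\u201c\u201d]", "\"", x)
  x <- gsub("[\u2018\u2019]", "'", x)
  x <- gsub("[\u2013\u2014\u2212]", "-", x)
  x <- gsub("\u00a0", " ", x)
  x <- gsub("[ \t\r\n\f\v]+", " ", x)
  trimws(x)
}

# tokens are runs of non-space non-punctuation characters, or a single
# sentence punctuation mark (. ; : ,) -- "(-)" survives as one token
.token_pattern <- "[.;:,]|[^ .;:,]+"

tokenize_offsets <- function(text) {
  m <- gregexpr(.token_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(token = character(0), start = integer(0), end = integer(0)))
  }
  len <- attr(m, "match.length")
  list(token = substring(text, m, m + len - 1L),
       start = as.integer(m), end = as.integer(m + len - 1L))
}

# contiguous subsequence test for multiword cues
has_token_seq <- function(window, cue_tokens) {
  k <- length(cue_tokens)
  n <- length(window)
  if (k == 0L || k > n) return(FALSE)
  for (i in seq_len(n - k + 1L)) {
    if (all(window[i:(i + k - 1L)] == cue_tokens)) return(TRUE)
  }
  FALSE
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# ---- matcher core ----------------------------------------------------------

# Finds all word-boundary occurrences of every lexicon phrase across a
# character vector of normalized texts, longest phrase first so that a
# longer phrase shadows any shorter phrase nested inside it. Returns a list
# (one element per text) of data.frames with columns term, start, end
# (0-based half-open) -- negation not yet assessed.
match_phrases_batch <- function(texts, phrases) {
  ord <- order(-nchar(phrases), seq_along(phrases))
  masked <- texts
  hits <- vector("list", length(texts))
  for (ph in phrases[ord]) {
    pat <- paste0("\\b", escape_regex(ph), "\\b")
    m <- gregexpr(pat, masked, perl = TRUE)
    for (i in seq_along(masked)) {
      mi <- m[[i]]
      if (mi[1] == -1L) next
      len <- attr(mi, "match.length")
      hits[[i]] <- rbind(hits[[i]],
                         data.frame(term = ph,
                                    start = as.integer(mi) - 1L,
                                    end = as.integer(mi) - 1L + len,
                                    stringsAsFactors = FALSE))
      # shadow matched spans so shorter phrases cannot rematch inside them
      regmatches(masked[i], list(mi)) <- list(strrep("\u0001", len))
    }
  }
  hits
}

# negation scope for one mention given the text's token table
mention_negated <- function(tok, m_start1, m_end1, lexicon,
                            pre_cues_tok, post_cues_tok) {
  w <- lexicon$window_tokens
  terms_idx <- which(tok$end >= m_start1 & tok$start <= m_end1)
  if (length(terms_idx) == 0L) return(FALSE)
  first <- terms_idx[1]
  last <- terms_idx[length(terms_idx)]
  # pre window: up to w tokens before, truncated after the last terminator
  lo <- max(1L, first - w)
  if (first > 1L) {
    win <- tok$token[lo:(first - 1L)]
    cut <- which(win %in% lexicon$scope_terminators)
    if (length(cut)) win <- if (max(cut) < length(win)) win[(max(cut) + 1L):length(win)] else character(0)
    for (cue in pre_cues_tok) {
      if (has_token_seq(win, cue)) return(TRUE)
    }
  }
  # post window: up to w tokens after, truncated before the first terminator
  n <- length(tok$token)
  if (last < n) {
    hi <- min(n, last + w)
    win <- tok$token[(last + 1L):hi]
    cut <- which(win %in% lexicon$scope_terminators)
    if (length(cut)) win <- win[seq_len(min(cut) - 1L)]
    for (cue in post_cues_tok) {
      if (has_token_seq(win, cue)) return(TRUE)
    }
  }
  FALSE
}

# sentence excerpt around a mention (bounded by '.' tokens)
mention_excerpt <- function(text, tok, m_start1, m_end1) {
  dots <- which(tok$token == ".")
  prev <- dots[tok$start[dots] < m_start1]
  nxt <- dots[tok$start[dots] >= m_end1]
  from <- if (length(prev)) tok$end[prev[length(prev)]] + 1L else 1L
  to <- if (length(nxt)) tok$end[nxt[1]] else nchar(text)
  trimws(substr(text, from, to))
}

mentions_for_text <- function(text, raw_hits, lexicon, negation = TRUE) {
  if (is.null(raw_hits) || nrow(raw_hits) == 0L) {
    return(empty_mentions())
  }
  raw_hits <- raw_hits[order(raw_hits$start), , drop = FALSE]
  tok <- tokenize_offsets(text)
  pre_cues_tok <- lapply(lexicon$negation_cues_pre,
                         function(c) tokenize_offsets(c)$token)
  post_cues_tok <- lapply(lexicon$negation_cues_post,
                          function(c) tokenize_offsets(c)$token)
  neg <- logical(nrow(raw_hits))
  exc <- character(nrow(raw_hits))
  for (j in seq_len(nrow(raw_hits))) {
    s1 <- raw_hits$start[j] + 1L        # 1-based inclusive
    e1 <- raw_hits$end[j]               # 1-based inclusive end
    if (negation) {
      neg[j] <- mention_negated(tok, s1, e1, lexicon, pre_cues_tok, post_cues_tok)
    }
    exc[j] <- mention_excerpt(text, tok, s1, e1)
  }
  data.frame(term = raw_hits$term, start = raw_hits$start, end = raw_hits$end,
             negated = neg, excerpt = exc, stringsAsFactors = FALSE)
}

empty_mentions <- function() {
  data.frame(term = character(0), start = integer(0), end = integer(0),
             negated = logical(0), excerpt = character(0),
             stringsAsFactors = FALSE)
}

#' Find complication term mentions in normalized text
#'
#' Locates every word-boundary occurrence of every lexicon phrase (longest
#' phrase first, so a phrase never double-counts inside a longer one) and
#' labels each occurrence `negated = TRUE` when a pre-position cue occurs
#' within `window_tokens` tokens before it, or a post-position cue within
#' `window_tokens` tokens after it, with no scope terminator intervening.
#'
#' @param text a single string, already passed through [normalize_text()].
#' @param lexicon a [term_lexicon()].
#' @return data.frame with columns `term`, `start`, `end` (0-based half-open
#'   character span in `text`), `negated`, `excerpt` (the containing
#'   sentence).
#' @examples
#' find_mentions("there was no lens touch", default_term_lexicon())
#' @export
find_mentions <- function(text, lexicon = default_term_lexicon()) {
  stopifnot(length(text) == 1L)
  raw <- match_phrases_batch(text, lexicon$complication_terms)[[1]]
  mentions_for_text(text, raw, lexicon)
}

# batched engine used by flag_corpus(); texts must be normalized
find_mentions_batch <- function(texts, lexicon, negation = TRUE) {
  raw <- match_phrases_batch(texts, lexicon$complication_terms)
  lapply(seq_along(texts), function(i) {
    mentions_for_text(texts[i], raw[[i]], lexicon, negation = negation)
  })
}

# ---- case-level flags ------------------------------------------------------

#' Compute per-case complication flags
#'
#' Searches the case's operative report body and all of its clinical notes
#' and raises the flag for a term iff at least one non-negated mention
#' exists. The raw `endophthalmitis` flag is kept here; separating
#' pre-existing from postoperative disease is the job of
#' [classify_endophthalmitis()].
#'
#' @param case a single manifest row (list or one-row data.frame) with at
#'   least `case_id`.
#' @param docs data.frame of the case's documents (columns `doc_id`,
#'   `kind`, `date`, `body`).
#' @param lexicon a [term_lexicon()].
#' @return list with `case_id`, `flags` (named logical over lexicon terms)
#'   and `mentions` (evidence data.frame with document context).
#' @export
flag_case <- function(case, docs, lexicon = default_term_lexicon()) {
  case_id <- as.character(case[["case_id"]])
  if (!any(docs$kind == "operative_report")) {
    stop(sprintf("case '%s' has no operative report among its documents", case_id),
         call. = FALSE)
  }
  texts <- normalize_text(docs$body)
  per_doc <- find_mentions_batch(texts, lexicon)
  nm <- vapply(per_doc, nrow, 0L)
  mentions <- do.call(rbind, per_doc)
  mentions$doc_id <- rep(docs$doc_id, nm)
  mentions$kind <- rep(docs$kind, nm)
  mentions$date <- rep(as_iso_date(docs$date), nm)
  mentions$case_id <- rep(case_id, nrow(mentions))
  flags <- vapply(lexicon$complication_terms, function(t) {
    any(mentions$term == t & !mentions$negated)
  }, logical(1))
  list(case_id = case_id, flags = flags, mentions = mentions)
}

#' Flag every case of a corpus
#'
#' Batch version of [flag_case()]: computes mentions for all documents
#' (deduplicating identical bodies) and aggregates per-case binary flags.
#'
#' @param manifest manifest data.frame (one row per case).
#' @param docs document data.frame (all cases).
#' @param lexicon a [term_lexicon()].
#' @return list with `flags` (data.frame: `case_id` plus one logical column
#'   per term) and `mentions` (data.frame of all mentions with `doc_id`,
#'   `case_id`, `kind`, `date`, span, `negated`, `excerpt`).
#' @export
flag_corpus <- function(manifest, docs, lexicon = default_term_lexicon()) {
  op_cases <- unique(docs$case_id[docs$kind == "operative_report"])
  missing <- setdiff(manifest$case_id, op_cases)
  if (length(missing)) {
    stop(sprintf("no operative report for case(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  texts <- normalize_text(docs$body)
  uniq <- unique(texts)
  idx <- match(texts, uniq)
  per_uniq <- find_mentions_batch(uniq, lexicon)
  per_doc <- per_uniq[idx]
  nm <- vapply(per_doc, nrow, 0L)
  mentions <- do.call(rbind, per_doc)
  mentions$doc_id <- rep(docs$doc_id, nm)
  mentions$case_id <- rep(docs$case_id, nm)
  mentions$kind <- rep(docs$kind, nm)
  mentions$date <- rep(as_iso_date(docs$date), nm)
  terms <- lexicon$complication_terms
  flags <- data.frame(case_id = manifest$case_id, stringsAsFactors = FALSE)
  pos <- mentions[!mentions$negated, , drop = FALSE]
  for (t in terms) {
    flags[[t]] <- flags$case_id %in% pos$case_id[pos$term == t]
  }
  list(flags = flags, mentions = mentions)
}

as_iso_date <- function(x) as.Date(x)

#' Write the flag spreadsheet
#'
#' One row per case with the binary flag per term plus a collapsed evidence
#' column quoting the non-negated sentence excerpts, mirroring the
#' reviewer-facing spreadsheet of the surveillance workflow.
#'
#' @param flagged result of [flag_corpus()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_flag_spreadsheet <- function(flagged, path) {
  out <- flagged$flags
  pos <- flagged$mentions[!flagged$mentions$negated, , drop = FALSE]
  ev <- vapply(out$case_id, function(cid) {
    paste(unique(pos$excerpt[pos$case_id == cid]), collapse = " | ")
  }, character(1))
  out$evidence <- ev
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
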