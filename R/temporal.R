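#' Classify endophthalmitis mentions relative to the biopsy date
#'
#' A case is `postoperative` iff at least one non-negated endophthalmitis
#' mention sits in a document dated strictly after the procedure date;
#' mentions on or before that date (including the operative report's own
#' indication text) are pre-existing. No mention at all is `none`.
#'
#' @param case one manifest row with `case_id`, `procedure_date`.
#' @param mentions data.frame of this case's mentions restricted to the
#'   term `endophthalmitis` with `negated == FALSE`; must carry a `date`
#'   column (document dates; `NA` dates are an error).
#' @return one-row data.frame: `case_id`, `n_mentions`,
#'   `earliest_mention_date`, `classification`.
#' @examples
#' case <- list(case_id = "C1", procedure_date = as.Date("2020-06-01"))
#' m <- data.frame(term = "endophthalmitis", negated = FALSE,
#'                 date = as.Date("2018-07-01"))
#' classify_endophthalmitis(case, m)
#' @export
classify_endophthalmitis <- function(case, mentions) {
  m <- mentions[mentions$term == "endophthalmitis" & !mentions$negated, ,
                drop = FALSE]
  if (nrow(m) > 0L && anyNA(m$date)) {
    stop(sprintf("undated document among endophthalmitis mentions of case '%s'",
                 case[["case_id"]]), call. = FALSE)
  }
  pdate <- as.Date(case[["procedure_date"]])
  cls <- if (nrow(m) == 0L) {
    "none"
  } else if (any(as.Date(m$date) > pdate)) {
    "postoperative"
  } else {
    "preexisting_only"
  }
  data.frame(case_id = as.character(case[["case_id"]]),
             n_mentions = nrow(m),
             earliest_mention_date = if (nrow(m)) min(as.Date(m$date)) else
               as.Date(NA),
             classification = cls,
             stringsAsFactors = FALSE)
}

#' Temporal endophthalmitis classification for a whole corpus
#'
#' @param manifest manifest data.frame.
#' @param mentions mention stream from [flag_corpus()] (all terms; the
#'   endophthalmitis subset is selected here).
#' @return data.frame with one row per case.
#' @export
endophthalmitis_temporal <- function(manifest, mentions) {
  m <- mentions[mentions$term == "endophthalmitis" & !mentions$negated, ,
                drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    classify_endophthalmitis(manifest[i, , drop = FALSE],
                             m[m$case_id == manifest$case_id[i], ,
                               drop = FALSE])
  }))
  rownames(out) <- NULL
  out
}

#' Follow-up retention and duration summary
#'
#' Computes each case's postoperative visit-day offsets (clinical notes
#' dated on/after the procedure date) and summarizes retention. Day-1
#' retention counts cases with a visit at offset exactly 1. Window
#' retention is reported under both readings of "followed-up for W":
#' `last_visit` (default; the case's last visit offset is at least W) and
#' `any_visit` (some visit falls in `[1, W]`).
#'
#' @param manifest manifest data.frame.
#' @param docs document data.frame; `clinical_note` rows must be dated.
#' @param windows named integer vector of window lengths in days.
#' @return list with `n`, `per_case` (case_id, `last_visit_day`, `n_visits`),
#'   `day1_count`, `day1_fraction`, `retention` (data.frame: window, days,
#'   count and fraction under both readings), `median_day`, `min_day`,
#'   `max_day`.
#' @export
followup_summary <- function(manifest, docs,
                             windows = c(week = 7L, month = 30L, quarter = 90L)) {
  notes <- docs[docs$kind == "clinical_note", , drop = FALSE]
  if (nrow(notes) > 0L && anyNA(notes$date)) {
    stop("undated clinical note; dates are mandatory", call. = FALSE)
  }
  pdate <- as.Date(manifest$procedure_date)[match(notes$case_id,
                                                  manifest$case_id)]
  offset <- as.integer(as.Date(notes$date) - pdate)
  keep <- !is.na(offset) & offset >= 0L
  notes <- notes[keep, , drop = FALSE]
  offset <- offset[keep]
  by_case <- split(offset, notes$case_id)
  last <- vapply(manifest$case_id, function(cid) {
    v <- by_case[[cid]]
    if (is.null(v)) 0L else max(v)
  }, integer(1))
  nvis <- vapply(manifest$case_id, function(cid) {
    length(by_case[[cid]])
  }, integer(1))
  day1 <- vapply(manifest$case_id, function(cid) {
    1L %in% by_case[[cid]]
  }, logical(1))
  n <- nrow(manifest)
  retention <- do.call(rbind, lapply(names(windows), function(w) {
    W <- windows[[w]]
    last_n <- sum(last >= W)
    any_n <- sum(vapply(manifest$case_id, function(cid) {
      any(by_case[[cid]] >= 1L & by_case[[cid]] <= W)
    }, logical(1)))
    data.frame(window = w, days = W,
               last_visit_count = last_n, last_visit_fraction = last_n / n,
               any_visit_count = any_n, any_visit_fraction = any_n / n,
               stringsAsFactors = FALSE)
  }))
  list(n = n,
       per_case = data.frame(case_id = manifest$case_id,
                             last_visit_day = unname(last),
                             n_visits = unname(nvis),
                             stringsAsFactors = FALSE),
       day1_count = sum(day1),
       day1_fraction = sum(day1) / n,
       retention = retention,
       median_day = as.numeric(stats::median(as.numeric(last))),
       min_day = min(last),
       max_day = max(last))
}
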