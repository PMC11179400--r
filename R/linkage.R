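#' Build the EHR patient directory used for record linkage
#'
#' One row per operative report: the EHR-side (true) MRN, normalized
#' patient name, DOB and report date. Linkage deliberately ignores any
#' shared case identifier: a manifest row is matched on identifiers and the
#' procedure date alone, as it would be against a real clinical repository.
#'
#' @param docs document data.frame.
#' @return data.frame `mrn`, `name_norm`, `dob`, `report_date`.
#' @export
build_ehr_index <- function(docs) {
  ops <- docs[docs$kind == "operative_report", , drop = FALSE]
  data.frame(mrn = as.character(ops$mrn),
             name_norm = normalize_person_name(ops$name),
             dob = as.Date(ops$dob),
             report_date = as.Date(ops$date),
             stringsAsFactors = FALSE)
}

# casefold, strip punctuation, collapse whitespace
normalize_person_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z ]", " ", x)
  trimws(gsub(" +", " ", x))
}

# MRN equality up to dropped leading zeros (value-equal, length differing
# by at most two digits)
mrn_zero_equal <- function(a, b) {
  if (a == b) return(TRUE)
  suppressWarnings({
    va <- as.numeric(a)
    vb <- as.numeric(b)
  })
  if (is.na(va) || is.na(vb)) return(FALSE)
  va == vb && abs(nchar(a) - nchar(b)) <= 2L
}

# wrong DOB explainable as a month/day transposition or a single-field edit
dob_explainable <- function(a, b) {
  la <- as.POSIXlt(a)
  lb <- as.POSIXlt(b)
  transposed <- la$year == lb$year && la$mon + 1L == lb$mday &&
    la$mday == lb$mon + 1L
  diffs <- sum(c(la$year != lb$year, la$mon != lb$mon, la$mday != lb$mday))
  transposed || diffs == 1L
}

name_explainable <- function(a, b) {
  utils::adist(a, b)[1, 1] <= 2L
}

#' Link one manifest row against the EHR patient directory
#'
#' An exact match requires agreement of MRN, normalized name and DOB plus
#' an operative report dated on the procedure date. Failing that, a
#' candidate must agree on at least two of the three identifiers, have a
#' same-date operative report, and the disagreeing field must be
#' explainable by a known data-entry corruption (MRN differing only by
#' leading zeros; DOB with transposed month/day or a single-field edit;
#' name within edit distance 2). A unique such candidate resolves the row;
#' two distinct candidate patients leave it unresolved with an ambiguity
#' note -- the linker never auto-picks.
#'
#' @param manifest_row one manifest row (list or one-row data.frame).
#' @param ehr_index output of [build_ehr_index()].
#' @return one-row data.frame: `case_id`, `status` (`exact_match`,
#'   `resolved`, `unresolved`), `discrepant_fields` (`;`-joined subset of
#'   mrn, name, dob), `resolution_note`.
#' @export
link_case <- function(manifest_row, ehr_index) {
  r <- manifest_row
  res <- function(status, fields = character(0), note = "") {
    data.frame(case_id = as.character(r[["case_id"]]), status = status,
               discrepant_fields = paste(fields, collapse = ";"),
               resolution_note = note, stringsAsFactors = FALSE)
  }
  nm <- normalize_person_name(r[["name"]])
  dob <- as.Date(r[["dob"]])
  pdate <- as.Date(r[["procedure_date"]])
  same_date <- ehr_index[ehr_index$report_date == pdate, , drop = FALSE]
  if (nrow(same_date) == 0L) {
    return(res("unresolved", note = "no operative report on the procedure date"))
  }
  agree <- cbind(mrn = same_date$mrn == r[["mrn"]],
                 name = same_date$name_norm == nm,
                 dob = same_date$dob == dob)
  n_agree <- rowSums(agree)
  if (any(n_agree == 3L)) {
    return(res("exact_match"))
  }
  cand <- which(n_agree == 2L)
  ok <- logical(length(cand))
  bad_field <- character(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    f <- colnames(agree)[!agree[i, ]]
    bad_field[k] <- f
    ok[k] <- switch(f,
                    mrn = mrn_zero_equal(r[["mrn"]], same_date$mrn[i]),
                    dob = dob_explainable(dob, same_date$dob[i]),
                    name = name_explainable(nm, same_date$name_norm[i]))
  }
  hit <- cand[ok]
  if (length(hit) == 0L) {
    return(res("unresolved", note = "no candidate satisfies the corruption rules"))
  }
  pat <- unique(same_date$mrn[hit])
  if (length(pat) > 1L) {
    return(res("unresolved",
               note = sprintf("ambiguous: %d EHR patients satisfy the resolution rule",
                              length(pat))))
  }
  f <- unique(bad_field[ok])
  res("resolved", fields = f,
      note = sprintf("resolved on 2 of 3 identifiers; %s explainable by entry error",
                     paste(f, collapse = "/")))
}

#' Link every manifest row of a corpus
#'
#' @param manifest manifest data.frame.
#' @param docs document data.frame (supplies the EHR index).
#' @return data.frame of [link_case()] results, one row per case.
#' @export
link_corpus <- function(manifest, docs) {
  index <- build_ehr_index(docs)
  out <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    link_case(manifest[i, , drop = FALSE], index)
  }))
  rownames(out) <- NULL
  out
}
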