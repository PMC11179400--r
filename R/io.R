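#' Write a corpus to disk
#'
#' Serializes the manifest as CSV, the documents as JSON-lines (one
#' document per line) and the ground truth as a JSON-lines sidecar keyed by
#' `case_id`. The sidecar is never read by the pipeline proper -- it exists
#' for tests and audit only. All dates are ISO-8601; serialization is
#' byte-stable, so identical corpora produce identical files.
#'
#' @param corpus an `ehr_corpus` from [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- corpus$manifest
  man$dob <- as.character(man$dob)
  man$procedure_date <- as.character(man$procedure_date)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)

  docs <- corpus$docs
  doc_lines <- vapply(seq_len(nrow(docs)), function(i) {
    d <- docs[i, ]
    rec <- list(doc_id = d$doc_id, case_id = d$case_id, mrn = d$mrn,
                name = d$name, dob = as.character(d$dob), kind = d$kind,
                date = as.character(d$date), body = d$body)
    if (d$kind == "operative_report") rec$anesthesia_text <- d$anesthesia_text
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(doc_lines, file.path(dir, "docs.jsonl"))

  tr <- corpus$truth
  truth_lines <- vapply(seq_len(nrow(tr)), function(i) {
    rec <- list(case_id = tr$case_id[i],
                anesthesia_true = tr$anesthesia_true[i],
                anesthesia_section_present = tr$anesthesia_section_present[i],
                general_misuse = tr$general_misuse[i],
                complications_true =
                  strsplit(tr$complications_true[i], ";")[[1]],
                has_preexisting_endophthalmitis =
                  tr$has_preexisting_endophthalmitis[i],
                identifier_corruption = tr$identifier_corruption[i],
                followup_days = as.integer(tr$followup_days[[i]]))
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(truth_lines, file.path(dir, "truth.jsonl"))
  invisible(dir)
}

#' Read a case manifest CSV
#' @param path manifest CSV path.
#' @return manifest data.frame with `Date` columns restored.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, colClasses = "character")
  man$dob <- as.Date(man$dob)
  man$procedure_date <- as.Date(man$procedure_date)
  man
}

#' Read a JSON-lines document file
#' @param path docs JSONL path.
#' @return document data.frame.
#' @export
read_docs <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  docs <- do.call(rbind, lapply(recs, function(r) {
    data.frame(doc_id = r$doc_id, case_id = r$case_id, mrn = r$mrn,
               name = r$name, dob = r$dob, kind = r$kind, date = r$date,
               anesthesia_text = r$anesthesia_text %||% "",
               body = r$body, stringsAsFactors = FALSE)
  }))
  docs$dob <- as.Date(docs$dob)
  docs$date <- as.Date(docs$date)
  docs
}

#' Read a ground-truth JSON-lines sidecar
#' @param path truth JSONL path.
#' @return truth data.frame (with `followup_days` as a list column).
#' @export
read_truth <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  out <- do.call(rbind, lapply(recs, function(r) {
    data.frame(case_id = r$case_id, anesthesia_true = r$anesthesia_true,
               anesthesia_section_present = r$anesthesia_section_present,
               general_misuse = r$general_misuse,
               complications_true =
                 paste(unlist(r$complications_true), collapse = ";"),
               has_preexisting_endophthalmitis =
                 r$has_preexisting_endophthalmitis,
               identifier_corruption = r$identifier_corruption,
               stringsAsFactors = FALSE)
  }))
  out$followup_days <- I(lapply(recs, function(r) as.integer(r$followup_days)))
  out
}
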