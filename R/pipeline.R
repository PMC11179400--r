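#' Run the full surveillance pipeline
#'
#' Executes the workflow end to end on a synthetic corpus: generate ->
#' link -> flag -> anesthesia -> temporal -> follow-up -> safety report ->
#' audit. Review resolutions for anesthesia cases flagged `needs_review` or
#' `no_hit` are taken from the planted ground truth, standing in for the
#' manual verification step of the workflow. The run is a pure function of
#' `(profile, seed)`.
#'
#' @param profile a [cohort_profile()]; default [default_profile()].
#' @param seed optional integer overriding `profile$seed` (also seeds the
#'   audit sample).
#' @param out_dir optional directory; when given, every stage's output is
#'   written there (corpus files, linkage CSV, flag spreadsheet, anesthesia
#'   calls CSV, temporal CSV, JSON summaries and a run manifest with
#'   provenance).
#' @param lexicon complication [term_lexicon()].
#' @param anesthesia_lexicon anesthesia token vector.
#' @param audit_fraction fraction of cases audited (default 500/1418).
#' @param strict if `TRUE` (default), any unresolved linkage aborts the run
#'   listing the case ids; if `FALSE`, unresolved cases are reported but the
#'   run continues.
#' @param adversarial passed to [generate_corpus()].
#' @return list with `corpus`, `links`, `flagged`, `anesthesia`
#'   (summary incl. per-case calls), `temporal`, `followup`, `report`,
#'   `audit`, `provenance`.
#' @examples
#' \donttest{
#' res <- run_pipeline(seed = 1)
#' res$report
#' }
#' @export
run_pipeline <- function(profile = default_profile(),
                         seed = NULL,
                         out_dir = NULL,
                         lexicon = default_term_lexicon(),
                         anesthesia_lexicon = default_anesthesia_lexicon(),
                         audit_fraction = 500 / 1418,
                         strict = TRUE,
                         adversarial = FALSE) {
  if (!is.null(seed)) profile$seed <- as.integer(seed)
  if (profile$n_cases == 0L) stop("no cases in profile", call. = FALSE)
  corpus <- generate_corpus(profile, adversarial = adversarial)

  links <- link_corpus(corpus$manifest, corpus$docs)
  unresolved <- links$case_id[links$status == "unresolved"]
  if (length(unresolved)) {
    msg <- sprintf("unresolved linkage for case(s): %s",
                   paste(unresolved, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  flagged <- flag_corpus(corpus$manifest, corpus$docs, lexicon)

  calls <- classify_corpus_anesthesia(corpus$manifest, corpus$docs,
                                      anesthesia_lexicon)
  review <- calls$needs_review | calls$no_hit
  resolutions <- data.frame(
    case_id = calls$case_id[review],
    final_label = corpus$truth$anesthesia_true[
      match(calls$case_id[review], corpus$truth$case_id)],
    stringsAsFactors = FALSE)
  anesthesia <- summarize_anesthesia(calls, resolutions)

  temporal <- endophthalmitis_temporal(corpus$manifest, flagged$mentions)
  followup <- followup_summary(corpus$manifest, corpus$docs)
  report <- complication_report(flagged$flags, temporal)
  audit_seed <- (profile$seed %% 2000000000L) + 1L
  audit <- run_audit(flagged$flags, corpus$truth, audit_fraction,
                     seed = audit_seed)

  provenance <- list(seed = profile$seed,
                     n_cases = profile$n_cases,
                     audit_fraction = audit_fraction,
                     audit_seed = audit_seed,
                     adversarial = adversarial,
                     package_version =
                       as.character(utils::packageVersion("aqsafe")))
  result <- list(corpus = corpus, links = links, flagged = flagged,
                 anesthesia = anesthesia, temporal = temporal,
                 followup = followup, report = report, audit = audit,
                 provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(result$corpus, file.path(out_dir, "corpus"))
  utils::write.csv(result$links, file.path(out_dir, "links.csv"),
                   row.names = FALSE)
  write_flag_spreadsheet(result$flagged, file.path(out_dir, "flags.csv"))
  m <- result$flagged$mentions
  m$date <- as.character(m$date)
  writeLines(vapply(seq_len(nrow(m)), function(i) {
    as.character(jsonlite::toJSON(as.list(m[i, ]), auto_unbox = TRUE))
  }, character(1)), file.path(out_dir, "mentions.jsonl"))
  utils::write.csv(result$anesthesia$cases,
                   file.path(out_dir, "anesthesia_calls.csv"),
                   row.names = FALSE)
  tmp <- result$temporal
  tmp$earliest_mention_date <- as.character(tmp$earliest_mention_date)
  utils::write.csv(tmp, file.path(out_dir, "temporal.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(provenance = result$provenance,
         followup = result$followup[c("n", "day1_count", "day1_fraction",
                                      "median_day", "min_day", "max_day")],
         retention = result$followup$retention,
         anesthesia = result$anesthesia[c("n", "n_no_hit", "no_hit_fraction",
                                          "n_general_term",
                                          "n_general_resolved_local",
                                          "auto_accuracy",
                                          "auto_accuracy_strict",
                                          "akinesia_count")],
         safety = list(n = result$report$n,
                       total_count = result$report$total_count,
                       total_rate_pct = result$report$total_rate_pct,
                       postop_endophthalmitis =
                         result$report$postop_endophthalmitis,
                       table = result$report$table),
         audit = list(audit_n = result$audit$audit_n,
                      overall_accuracy = result$audit$overall_accuracy,
                      intraop_accuracy = result$audit$intraop_accuracy,
                      per_flag = result$audit$per_flag)),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
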