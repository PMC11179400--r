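test_that("planted category counts are conserved exactly across seeds", {
  for (seed in c(3L, 104729L)) {
    for (p in list(small_profile(seed = seed),
                   small_profile(n_cases = 25L, seed = seed,
                                 n_identifier_mismatches = 2L,
                                 mismatch_split = c(mrn_leading_zero = 1L,
                                                    dob_wrong = 1L,
                                                    name_misspelled = 0L)))) {
      corp <- generate_corpus(p)
      tr <- corp$truth
      expect_identical(nrow(corp$manifest), p$n_cases)
      expect_identical(length(unique(corp$docs$mrn)), p$n_patients)
      expect_identical(sum(tr$identifier_corruption != "none"),
                       p$n_identifier_mismatches)
      expect_identical(sum(tr$has_preexisting_endophthalmitis),
                       p$n_preexisting_endophthalmitis)
      expect_identical(sum(tr$general_misuse), p$n_general_misuse)
      expect_identical(sum(nzchar(tr$complications_true)),
                       p$n_true_complications)
      expect_equal(as.vector(table(tr$anesthesia_true)[names(sort(p$anesthesia_mix))]),
                   as.vector(sort(p$anesthesia_mix)))
      ops <- corp$docs[corp$docs$kind == "operative_report", ]
      expect_identical(sum(grepl("\\bgeneral\\b", ops$anesthesia_text)),
                       p$n_general_term_total)
      no_hit <- !nzchar(ops$anesthesia_text) |
        ops$anesthesia_text == corpus_templates()$anesthesia_no_hit_text
      expect_identical(sum(no_hit), p$n_no_hit_anesthesia)
      ld <- tr$last_visit_day
      expect_identical(sum(ld >= 7L), p$followup$week)
      expect_identical(sum(ld >= 30L), p$followup$month)
      expect_identical(sum(ld >= 90L), p$followup$quarter)
      expect_identical(sum(vapply(tr$followup_days, function(d) 1L %in% d,
                                  logical(1))),
                       p$followup$day1)
    }
  }
})

test_that("every case has exactly one operative report dated on the procedure date", {
  corp <- generate_corpus(small_profile())
  ops <- corp$docs[corp$docs$kind == "operative_report", ]
  expect_identical(sort(ops$case_id), sort(corp$manifest$case_id))
  expect_identical(ops$date[match(corp$manifest$case_id, ops$case_id)],
                   corp$manifest$procedure_date)
})

test_that("identical profiles give byte-identical serialized corpora", {
  p <- small_profile(seed = 11L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_corpus(generate_corpus(p), d1)
  write_corpus(generate_corpus(p), d2)
  for (f in c("manifest.csv", "docs.jsonl", "truth.jsonl")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(
    generate_corpus(small_profile(seed = 11L))$manifest$mrn,
    generate_corpus(small_profile(seed = 12L))$manifest$mrn))
})

test_that("corpus round-trips through the on-disk formats", {
  corp <- generate_corpus(small_profile(seed = 5L))
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  docs <- read_docs(file.path(dir, "docs.jsonl"))
  tr <- read_truth(file.path(dir, "truth.jsonl"))
  expect_equal(man, corp$manifest)
  expect_equal(docs[order(docs$doc_id), names(corp$docs)],
               corp$docs[order(corp$docs$doc_id), ],
               ignore_attr = TRUE)
  expect_identical(tr$anesthesia_true, corp$truth$anesthesia_true)
  expect_identical(lapply(tr$followup_days, as.integer),
                   lapply(corp$truth$followup_days, as.integer))
})

test_that("an empty profile yields an empty corpus", {
  p <- cohort_profile(
    n_cases = 0L, n_patients = 0L, n_surgeons = 1L,
    diagnosis_mix = data.frame(diagnosis = character(0), count = integer(0)),
    anesthesia_mix = c(topical = 0L, peribulbar = 0L, subtenon = 0L,
                       retrobulbar = 0L, general = 0L),
    followup = list(day1 = 0L, week = 0L, month = 0L, quarter = 0L,
                    median_day = NA, max_day = 10L))
  corp <- generate_corpus(p)
  expect_identical(nrow(corp$manifest), 0L)
  expect_identical(nrow(corp$docs), 0L)
})

test_that("templates are sound: clean corpora carry only negated mentions", {
  p <- small_profile(n_true_complications = 0L,
                     n_general_misuse = 0L,
                     n_general_term_total = 1L,
                     n_no_hit_anesthesia = 0L,
                     n_preexisting_endophthalmitis = 1L,
                     diagnosis_mix = data.frame(diagnosis = "cataract",
                                                count = 40L),
                     n_identifier_mismatches = 0L,
                     mismatch_split = c(mrn_leading_zero = 0L, dob_wrong = 0L,
                                        name_misspelled = 0L))
  # the only non-negated mentions allowed are the planted pre-existing
  # endophthalmitis notes
  corp <- generate_corpus(p)
  flagged <- flag_corpus(corp$manifest, corp$docs)
  pos <- flagged$mentions[!flagged$mentions$negated, ]
  expect_true(all(pos$term == "endophthalmitis"))
  intra <- setdiff(default_term_lexicon()$complication_terms,
                   "endophthalmitis")
  expect_false(any(as.matrix(flagged$flags[intra])))
})

test_that("the planted complication case carries affirmative language", {
  corp <- generate_corpus(small_profile())
  cid <- corp$truth$case_id[nzchar(corp$truth$complications_true)]
  body <- corp$docs$body[corp$docs$case_id == cid &
                           corp$docs$kind == "operative_report"]
  expect_match(body, "a small descemet membrane tear was noted")
})

test_that("adversarial mode injects benign homonyms", {
  corp <- generate_corpus(small_profile(), adversarial = TRUE)
  expect_true(any(grepl("tear film", corp$docs$body, fixed = TRUE)))
})
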