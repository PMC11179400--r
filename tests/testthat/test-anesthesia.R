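test_that("anesthesia section extraction passes text through and flags absence", {
  rep1 <- list(kind = "operative_report",
               anesthesia_text = "topical anesthesia with intracameral lidocaine")
  expect_identical(extract_anesthesia_text(rep1),
                   "topical anesthesia with intracameral lidocaine")
  expect_identical(extract_anesthesia_text(
    list(kind = "operative_report", anesthesia_text = "")), NA_character_)
  expect_identical(extract_anesthesia_text(
    list(kind = "operative_report", anesthesia_text = "monitored anesthesia care")),
    "monitored anesthesia care")
  expect_error(extract_anesthesia_text(list(kind = "clinical_note",
                                            anesthesia_text = "x")))
})

test_that("the classification rule table behaves as specified", {
  c1 <- classify_anesthesia("topical anesthesia with intracameral lidocaine")
  expect_identical(c1$auto_label, "topical")
  expect_false(c1$needs_review)
  expect_false(c1$akinesia)

  c2 <- classify_anesthesia("monitored anesthesia care")
  expect_true(c2$no_hit)
  expect_identical(c2$auto_label, "unknown")
  expect_true(c2$needs_review)
  expect_identical(c2$review_reason, "no_hit")

  c3 <- classify_anesthesia(NA_character_)
  expect_true(c3$no_hit)

  c4 <- classify_anesthesia(
    "transient general anesthesia with intravenous sedation, topical drops")
  expect_true(grepl("general", c4$matched_terms))
  expect_true(grepl("topical", c4$matched_terms))
  expect_true(c4$needs_review)
  expect_identical(c4$review_reason, "general_ambiguous")
  expect_identical(c4$auto_label, "topical")

  c5 <- classify_anesthesia("general endotracheal anesthesia")
  expect_identical(c5$auto_label, "general")
  expect_true(c5$akinesia)
  expect_false(c5$needs_review)

  # adjunct terms alone cannot decide a label
  c6 <- classify_anesthesia("2% lidocaine gel")
  expect_identical(c6$auto_label, "unknown")
  expect_identical(c6$review_reason, "conflicting_terms")

  # the deepest block outranks topical prep drops
  c7 <- classify_anesthesia("retrobulbar block after topical proparacaine drops")
  expect_identical(c7$auto_label, "retrobulbar")
  expect_true(c7$akinesia)

  c8 <- classify_anesthesia("peribulbar block with lidocaine")
  expect_identical(c8$auto_label, "peribulbar")
  expect_false(c8$akinesia)
})

test_that("summaries partition cases and apply review resolutions", {
  corp <- generate_corpus(small_profile(seed = 21L))
  calls <- classify_corpus_anesthesia(corp$manifest, corp$docs)
  review <- calls$needs_review | calls$no_hit
  res <- data.frame(case_id = calls$case_id[review],
                    final_label = corp$truth$anesthesia_true[
                      match(calls$case_id[review], corp$truth$case_id)])
  s <- summarize_anesthesia(calls, res)
  expect_identical(sum(s$label_counts), s$n)
  expect_identical(unname(s$label_counts["unknown"]), 0L)
  p <- corp$profile
  expect_identical(s$n_no_hit, p$n_no_hit_anesthesia)
  expect_identical(s$n_general_term, p$n_general_term_total)
  expect_identical(s$n_general_resolved_local, p$n_general_misuse)
  expect_identical(s$akinesia_count,
                   unname(p$anesthesia_mix["retrobulbar"] +
                            p$anesthesia_mix["general"]))
  # misclassification is confined to the review pathway
  expect_identical(s$auto_accuracy_non_review, 1)
  expect_identical(s$auto_accuracy, 1 - s$n_no_hit / s$n)
})

test_that("a single unambiguous topical case summarizes trivially", {
  calls <- cbind(case_id = "C1",
                 classify_anesthesia("topical anesthesia with lidocaine"))
  s <- summarize_anesthesia(calls)
  expect_identical(s$auto_accuracy, 1)
  expect_identical(s$akinesia_fraction, 0)
})

test_that("duplicate case ids are rejected", {
  calls <- rbind(
    cbind(case_id = "C1", classify_anesthesia("topical drops")),
    cbind(case_id = "C1", classify_anesthesia("topical drops")))
  expect_error(summarize_anesthesia(calls), "duplicate")
})
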