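lex <- default_term_lexicon()

test_that("normalization folds case, whitespace, and unicode punctuation", {
  expect_identical(normalize_text("No Lens  Touch"), "no lens touch")
  expect_identical(normalize_text("“endophthalmitis”"),
                   "\"endophthalmitis\"")
  expect_identical(normalize_text(""), "")
  expect_identical(normalize_text("a—b – c"), "a-b - c")
})

test_that("mentions are found with correct spans and negation labels", {
  m <- find_mentions("there was no lens touch", lex)
  expect_identical(m$term, "lens touch")
  expect_true(m$negated)
  expect_identical(substr("there was no lens touch", m$start + 1L, m$end),
                   "lens touch")

  m <- find_mentions("a small descemet membrane tear was noted", lex)
  expect_identical(m$term, "tear")
  expect_false(m$negated)

  # a sentence boundary between a negation context and the term blocks scope
  m <- find_mentions("wound was watertight. tear of descemet membrane", lex)
  expect_identical(m$term, "tear")
  expect_false(m$negated)

  m <- find_mentions("no bleeding, no hyphema, chamber remained deep", lex)
  expect_setequal(m$term, c("bleeding", "hyphema"))
  expect_true(all(m$negated))
  expect_false("shallow" %in% m$term)
})

test_that("matching respects word boundaries and longest-phrase-first order", {
  expect_identical(nrow(find_mentions("tears were streaming", lex)), 0L)
  expect_identical(nrow(find_mentions("shallowing of the chamber", lex)), 0L)
  # user-extended lexicon where one phrase nests in another
  lex2 <- term_lexicon(c("touch", "lens touch"))
  m <- find_mentions("there was no lens touch", lex2)
  expect_identical(m$term, "lens touch")
  m2 <- find_mentions("no touch of the lens", lex2)
  expect_identical(m2$term, "touch")
})

test_that("excerpts quote the containing sentence", {
  m <- find_mentions(
    "the chamber stayed formed. a descemet tear was seen. wound closed.", lex)
  expect_identical(m$excerpt, "a descemet tear was seen.")
})

test_that("negation scope agrees with the brute-force oracle on an enumerated grammar", {
  cases <- negation_grammar_cases(lex)
  expect_gte(length(cases), 1000L)
  mismatches <- 0L
  for (cs in cases) {
    m <- find_mentions(cs$text, lex)
    m <- m[m$term == cs$term, , drop = FALSE]
    expect_identical(nrow(m), 1L)
    want <- oracle_negated(cs$tokens, cs$at, cs$term_len, lex)
    if (!identical(m$negated, want)) mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("flags are monotone: extra documents never clear a flag", {
  corp <- generate_corpus(small_profile(seed = 8L))
  flagged <- flag_corpus(corp$manifest, corp$docs)
  extra <- corp$docs[corp$docs$kind == "clinical_note", ][1:10, ]
  extra$doc_id <- paste0(extra$doc_id, "-DUP")
  extra$body <- "a descemet membrane tear was seen today."
  flagged2 <- flag_corpus(corp$manifest, rbind(corp$docs, extra))
  for (t in lex$complication_terms) {
    expect_true(all(flagged2$flags[[t]] >= flagged$flags[[t]]))
  }
})

test_that("a case without an operative report is rejected by name", {
  corp <- generate_corpus(small_profile())
  notes <- corp$docs[corp$docs$kind == "clinical_note", ]
  expect_error(
    flag_case(corp$manifest[1, ], notes[notes$case_id == corp$manifest$case_id[1], ]),
    corp$manifest$case_id[1])
  expect_error(flag_corpus(corp$manifest, notes), "no operative report")
})

test_that("flags recover the planted truth exactly on a clean corpus", {
  for (seed in c(2L, 31L)) {
    corp <- generate_corpus(small_profile(seed = seed))
    flagged <- flag_corpus(corp$manifest, corp$docs)
    tr <- corp$truth[match(flagged$flags$case_id, corp$truth$case_id), ]
    intra <- setdiff(lex$complication_terms, "endophthalmitis")
    for (t in intra) {
      want <- vapply(strsplit(tr$complications_true, ";"),
                     function(s) t %in% s, logical(1))
      expect_identical(flagged$flags[[t]], want)
    }
    expect_identical(flagged$flags$endophthalmitis,
                     tr$has_preexisting_endophthalmitis)
  }
})
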