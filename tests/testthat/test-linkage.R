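mk_index <- function(mrn, name, dob, date) {
  data.frame(mrn = mrn, name_norm = name, dob = as.Date(dob),
             report_date = as.Date(date), stringsAsFactors = FALSE)
}

row1 <- list(case_id = "C1", mrn = "0123456", name = "alma abbott",
             dob = as.Date("1950-03-10"),
             procedure_date = as.Date("2020-06-01"))

test_that("agreeing identifiers with a same-date report match exactly", {
  idx <- mk_index("0123456", "alma abbott", "1950-03-10", "2020-06-01")
  out <- link_case(row1, idx)
  expect_identical(out$status, "exact_match")
  expect_identical(out$discrepant_fields, "")
})

test_that("known entry errors are detected and resolved field by field", {
  # missing leading zero in the manifest MRN
  r <- row1
  r$mrn <- "123456"
  idx <- mk_index("0123456", "alma abbott", "1950-03-10", "2020-06-01")
  out <- link_case(r, idx)
  expect_identical(out$status, "resolved")
  expect_identical(out$discrepant_fields, "mrn")

  # transposed month/day in the DOB
  idx <- mk_index("0123456", "alma abbott", "1950-10-03", "2020-06-01")
  out <- link_case(row1, idx)
  expect_identical(out$status, "resolved")
  expect_identical(out$discrepant_fields, "dob")

  # single-field DOB edit
  idx <- mk_index("0123456", "alma abbott", "1950-03-11", "2020-06-01")
  expect_identical(link_case(row1, idx)$status, "resolved")

  # misspelled name within edit distance 2
  idx <- mk_index("0123456", "alma abbot", "1950-03-10", "2020-06-01")
  out <- link_case(row1, idx)
  expect_identical(out$status, "resolved")
  expect_identical(out$discrepant_fields, "name")
})

test_that("decoys and unexplainable mismatches never produce a false link", {
  # a second patient differing in two identifiers is not a candidate
  idx <- mk_index(c("9999999"), c("alma abbott"), "1980-01-01", "2020-06-01")
  expect_identical(link_case(row1, idx)$status, "unresolved")
  # one mismatching field, but not explainable by a corruption rule
  idx <- mk_index("7654321", "alma abbott", "1950-03-10", "2020-06-01")
  expect_identical(link_case(row1, idx)$status, "unresolved")
  # no operative report on the procedure date
  idx <- mk_index("0123456", "alma abbott", "1950-03-10", "2020-06-02")
  expect_identical(link_case(row1, idx)$status, "unresolved")
})

test_that("two candidate patients leave the case unresolved with a note", {
  r <- row1
  r$mrn <- "123456"
  idx <- rbind(
    mk_index("0123456", "alma abbott", "1950-03-10", "2020-06-01"),
    mk_index("123456",  "alma abbotz", "1950-03-10", "2020-06-01"))
  # candidate 1: name+dob agree, mrn zero-explainable;
  # candidate 2: mrn+dob agree, name within edit distance 2
  out <- link_case(r, idx)
  expect_identical(out$status, "unresolved")
  expect_match(out$resolution_note, "ambiguous")
})

test_that("generator corruption is always recoverable by the matching rule", {
  for (seed in c(4L, 77L, 2024L)) {
    corp <- generate_corpus(small_profile(seed = seed))
    links <- link_corpus(corp$manifest, corp$docs)
    tr <- corp$truth[match(links$case_id, corp$truth$case_id), ]
    expect_identical(sum(links$status != "exact_match"),
                     corp$profile$n_identifier_mismatches)
    expect_identical(sum(links$status == "unresolved"), 0L)
    corrupted <- tr$identifier_corruption != "none"
    expect_identical(links$status[corrupted],
                     rep("resolved", sum(corrupted)))
    field_of <- c(mrn_leading_zero = "mrn", dob_wrong = "dob",
                  name_misspelled = "name")
    expect_identical(links$discrepant_fields[corrupted],
                     unname(field_of[tr$identifier_corruption[corrupted]]))
  }
})
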