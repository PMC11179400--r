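test_that("Clopper-Pearson bounds match closed forms and the exact-test oracle", {
  # zero events: upper bound has the closed form 1 - (alpha/2)^(1/n)
  ci <- clopper_pearson(0, 100)
  expect_identical(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], 1 - 0.025^(1 / 100), tolerance = 1e-12)
  expect_equal(100 * ci[["upper"]], 3.62, tolerance = 1e-2)

  # independent oracle: stats::binom.test's exact interval
  grid <- expand.grid(x = c(0L, 1L, 2L, 17L, 50L, 100L),
                      n = c(100L, 1418L), conf = c(0.95, 0.99))
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; n <- grid$n[i]; conf <- grid$conf[i]
    ours <- clopper_pearson(x, n, conf)
    oracle <- stats::binom.test(x, n, conf.level = conf)$conf.int
    expect_equal(unname(ours), as.numeric(oracle), tolerance = 1e-6)
  }
  expect_error(clopper_pearson(1, 0))
  expect_error(clopper_pearson(5, 4))
})

test_that("the exact interval attains near-nominal coverage for rare events", {
  set.seed(1234)
  p <- 0.001
  n <- 1418L
  hits <- vapply(seq_len(200), function(i) {
    x <- stats::rbinom(1, n, p)
    ci <- clopper_pearson(x, n)
    ci[["lower"]] <= p && p <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

mk_flags <- function(n, tear_cases = integer(0)) {
  terms <- default_term_lexicon()$complication_terms
  out <- data.frame(case_id = sprintf("C%d", seq_len(n)))
  for (t in terms) out[[t]] <- rep(FALSE, n)
  out[["tear"]][tear_cases] <- TRUE
  out
}

mk_temporal <- function(n, postop = integer(0)) {
  data.frame(case_id = sprintf("C%d", seq_len(n)),
             classification = ifelse(seq_len(n) %in% postop,
                                     "postoperative", "none"))
}

test_that("the safety report tabulates counts, rates and intervals coherently", {
  rep <- complication_report(mk_flags(1418, tear_cases = 5L),
                             mk_temporal(1418))
  expect_identical(rep$total_count, 1L)
  expect_equal(round(rep$total_rate_pct, 2), 0.07)
  tear_row <- rep$table[rep$table$term == "tear", ]
  expect_identical(tear_row$count, 1L)
  expect_identical(tear_row$rate_display, "0.07%")
  expect_true(all(rep$table$ci_lower_pct <= rep$table$rate_pct + 1e-12))
  expect_true(all(rep$table$rate_pct <= rep$table$ci_upper_pct + 1e-12))
  # per-complication counts sum to the total row when events do not co-occur
  expect_identical(sum(rep$table$count), rep$total_count)
  expect_identical(rep$postop_endophthalmitis, 0L)

  rep2 <- complication_report(mk_flags(100), mk_temporal(100, postop = 7L))
  expect_identical(rep2$postop_endophthalmitis, 1L)
  expect_identical(rep2$total_count, 1L)

  expect_error(complication_report(mk_flags(0), mk_temporal(0)), "no cases")
})

mk_truth <- function(n, tear_cases = integer(0), endo_cases = integer(0)) {
  data.frame(case_id = sprintf("C%d", seq_len(n)),
             complications_true = ifelse(seq_len(n) %in% tear_cases, "tear", ""),
             has_preexisting_endophthalmitis = seq_len(n) %in% endo_cases)
}

test_that("audit arithmetic is exact and seeded", {
  flags <- mk_flags(100, tear_cases = 3L)
  truth <- mk_truth(100, tear_cases = 3L)
  a <- run_audit(flags, truth, 1.0, seed = 5L)
  expect_identical(a$audit_n, 100L)
  expect_identical(a$overall_accuracy, 1)

  # one planted disagreement in a fully audited 100-case corpus
  truth_bad <- mk_truth(100, tear_cases = c(3L, 50L))
  a2 <- run_audit(flags, truth_bad, 1.0, seed = 5L)
  expect_equal(a2$overall_accuracy, 0.99)
  expect_identical(a2$per_flag$false_negatives[a2$per_flag$term == "tear"], 1L)

  a3 <- run_audit(flags, truth, 500 / 1418, seed = 9L)
  expect_identical(a3$audit_n, as.integer(round(100 * 500 / 1418)))
  a4 <- run_audit(flags, truth, 500 / 1418, seed = 9L)
  expect_identical(a3$sampled_case_ids, a4$sampled_case_ids)

  expect_error(run_audit(flags, truth, 0), "audit_fraction")
  expect_error(run_audit(flags, truth, 1.2), "audit_fraction")
})
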