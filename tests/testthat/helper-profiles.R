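# Small, fast cohort profiles for unit tests. The defaults keep every
# planted phenomenon present at miniature scale.

small_profile <- function(n_cases = 40L, seed = 42L, ...) {
  n <- as.integer(n_cases)
  args <- list(
    n_cases = n,
    n_patients = n - 4L,
    n_repeat_patients = 4L,
    n_surgeons = 3L,
    diagnosis_mix = data.frame(
      diagnosis = c("cataract", "glaucoma", "endophthalmitis"),
      count = c(n - 3L, 2L, 1L)),
    anesthesia_mix = c(topical = n - 6L, peribulbar = 2L, subtenon = 1L,
                       retrobulbar = 2L, general = 1L),
    technique_needle_fraction = 0.6,
    n_no_hit_anesthesia = 2L,
    n_general_term_total = 2L,
    n_general_misuse = 1L,
    n_preexisting_endophthalmitis = 2L,
    n_true_complications = 1L,
    n_identifier_mismatches = 3L,
    mismatch_split = c(mrn_leading_zero = 1L, dob_wrong = 1L,
                       name_misspelled = 1L),
    followup = list(day1 = n - 2L, week = n - 5L, month = n - 10L,
                    quarter = n - 20L, median_day = NA, max_day = 300L),
    seed = as.integer(seed))
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_profile, args)
}

# Randomized valid profile used by property suites.
random_profile <- function(seed) {
  set.seed(seed)
  n <- sample(14:50, 1)
  n_rep <- sample(0:2, 1)
  g <- sample(0:2, 1)
  m <- sample(0:1, 1)
  e <- sample(0:1, 1)
  p <- e + sample(0:1, 1)
  comp <- sample(0:1, 1)
  k <- sample(0:3, 1)
  # keep specials within the single-case patient pool
  while (p + comp + k > (n - n_rep) - n_rep) k <- max(0L, k - 1L)
  week <- sample(0:n, 1)
  month <- sample(0:week, 1)
  quarter <- sample(0:month, 1)
  day1 <- if (week > 0) sample(seq_len(week), 1) else 0L
  nohit <- sample(0:2, 1)
  topical <- n - g - 3L
  nohit <- min(nohit, n - (g + m) - m)
  cohort_profile(
    n_cases = n, n_patients = n - n_rep, n_repeat_patients = n_rep,
    n_surgeons = 2L,
    diagnosis_mix = data.frame(diagnosis = c("cataract", "endophthalmitis"),
                               count = c(n - e, e)),
    anesthesia_mix = c(topical = topical, peribulbar = 1L, subtenon = 1L,
                       retrobulbar = 1L, general = g),
    technique_needle_fraction = runif(1),
    n_no_hit_anesthesia = nohit,
    n_general_term_total = g + m,
    n_general_misuse = m,
    n_preexisting_endophthalmitis = p,
    n_true_complications = comp,
    n_identifier_mismatches = k,
    followup = list(day1 = day1, week = week, month = month,
                    quarter = quarter, median_day = NA,
                    max_day = sample(120:500, 1)),
    seed = seed)
}
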