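#' Cohort profile for the synthetic EHR corpus generator
#'
#' A `cohort_profile` fixes every planted quantity of a synthetic biobank
#' cohort: how many cases and patients, the diagnosis and anesthesia mix,
#' how many operative reports carry an uninformative anesthesia section,
#' how many misuse the word "general" for sedated local anesthesia, how many
#' patients were seen for endophthalmitis before their biopsy, how many
#' manifest rows carry data-entry errors, the single (or more) true
#' intraoperative complications, and the follow-up visit schedule.
#' All category counts are planted exactly -- the generator assigns them,
#' it does not sample them -- so corpus-level tallies are seed-independent.
#'
#' @param n_cases total number of biopsy cases (manifest rows).
#' @param n_patients number of distinct patients; patients beyond
#'   `n_cases - n_repeat_patients` do not exist. Each of the
#'   `n_repeat_patients` repeat patients owns exactly two cases, so
#'   `n_patients + n_repeat_patients == n_cases` must hold.
#' @param n_repeat_patients patients contributing two cases (fellow eye or a
#'   later procedure).
#' @param n_surgeons distinct surgeons; each surgeon uses a single biopsy
#'   technique for all of their cases.
#' @param diagnosis_mix data.frame with columns `diagnosis`, `count`;
#'   counts must sum to `n_cases`.
#' @param anesthesia_mix named integer vector with names `topical`,
#'   `peribulbar`, `subtenon`, `retrobulbar`, `general`; the *true* final
#'   anesthesia labels, summing to `n_cases`.
#' @param technique_needle_fraction proportion of cases biopsied with a
#'   30-gauge needle (the rest use a blunt cannula via a corneal incision).
#' @param n_no_hit_anesthesia cases whose anesthesia section is empty or
#'   contains only uninformative text ("monitored anesthesia care").
#' @param n_general_term_total cases whose anesthesia text contains the word
#'   "general". Must equal `anesthesia_mix["general"] + n_general_misuse`.
#' @param n_general_misuse cases whose text says "transient general
#'   anesthesia" with intravenous sedation although the true label is a
#'   local type (planted as topical).
#' @param n_preexisting_endophthalmitis cases whose patient record contains a
#'   non-negated "endophthalmitis" mention dated on/before the procedure;
#'   must be at least the `endophthalmitis` count of `diagnosis_mix`, since
#'   surgical-indication mentions are included.
#' @param n_true_complications cases with an affirmative Descemet membrane
#'   tear in the operative report (all other cases carry only negated
#'   complication phrases).
#' @param n_identifier_mismatches manifest rows with a corrupted identifier;
#'   split across corruption types by `mismatch_split`.
#' @param mismatch_split named integer vector with names `mrn_leading_zero`,
#'   `dob_wrong`, `name_misspelled`, summing to `n_identifier_mismatches`.
#' @param followup named list with integer counts `day1` (cases with a visit
#'   at postoperative day 1), `week`, `month`, `quarter` (cases whose *last*
#'   visit is at day >= 7, 30, 90), and day parameters `median_day`,
#'   `max_day` for the last-visit distribution (either may be `NA` to leave
#'   it unconstrained).
#' @param seed integer seed; the corpus is a pure function of the profile
#'   including this seed.
#'
#' @return an object of class `cohort_profile` (a validated list).
#' @seealso [default_profile()], [generate_corpus()]
#' @export
cohort_profile <- function(n_cases,
                           n_patients,
                           n_repeat_patients = n_cases - n_patients,
                           n_surgeons = 2L,
                           diagnosis_mix,
                           anesthesia_mix,
                           technique_needle_fraction = 0.5,
                           n_no_hit_anesthesia = 0L,
                           n_general_term_total = unname(anesthesia_mix["general"]),
                           n_general_misuse = 0L,
                           n_preexisting_endophthalmitis = 0L,
                           n_true_complications = 0L,
                           n_identifier_mismatches = 0L,
                           mismatch_split = NULL,
                           followup = list(day1 = n_cases, week = n_cases,
                                           month = n_cases, quarter = n_cases,
                                           median_day = NA, max_day = 400L),
                           seed = 1L) {
  if (is.null(mismatch_split)) {
    mismatch_split <- split_evenly(n_identifier_mismatches)
  }
  profile <- structure(
    list(n_cases = as.integer(n_cases),
         n_patients = as.integer(n_patients),
         n_repeat_patients = as.integer(n_repeat_patients),
         n_surgeons = as.integer(n_surgeons),
         diagnosis_mix = diagnosis_mix,
         anesthesia_mix = anesthesia_mix,
         technique_needle_fraction = technique_needle_fraction,
         n_no_hit_anesthesia = as.integer(n_no_hit_anesthesia),
         n_general_term_total = as.integer(n_general_term_total),
         n_general_misuse = as.integer(n_general_misuse),
         n_preexisting_endophthalmitis = as.integer(n_preexisting_endophthalmitis),
         n_true_complications = as.integer(n_true_complications),
         n_identifier_mismatches = as.integer(n_identifier_mismatches),
         mismatch_split = mismatch_split,
         followup = followup,
         seed = as.integer(seed)),
    class = "cohort_profile")
  validate_profile(profile)
  profile
}

# near-even split of n mismatches over the three corruption types
split_evenly <- function(n) {
  n <- as.integer(n)
  base <- n %/% 3L
  extra <- n %% 3L
  c(mrn_leading_zero = base + as.integer(extra >= 1L),
    dob_wrong = base + as.integer(extra >= 2L),
    name_misspelled = base)
}

#' Validate a cohort profile
#'
#' Checks every structural invariant of a [cohort_profile()]; the error
#' message names the offending field.
#'
#' @param profile a `cohort_profile`.
#' @return `profile`, invisibly, if valid; otherwise an error.
#' @export
validate_profile <- function(profile) {
  p <- profile
  fail <- function(field, why) {
    stop(sprintf("invalid cohort profile: field '%s' %s", field, why),
         call. = FALSE)
  }
  counts <- c(n_cases = p$n_cases, n_patients = p$n_patients,
              n_repeat_patients = p$n_repeat_patients,
              n_surgeons = p$n_surgeons,
              n_no_hit_anesthesia = p$n_no_hit_anesthesia,
              n_general_term_total = p$n_general_term_total,
              n_general_misuse = p$n_general_misuse,
              n_preexisting_endophthalmitis = p$n_preexisting_endophthalmitis,
              n_true_complications = p$n_true_complications,
              n_identifier_mismatches = p$n_identifier_mismatches)
  for (nm in names(counts)) {
    if (is.na(counts[[nm]]) || counts[[nm]] < 0L) fail(nm, "must be a non-negative count")
  }
  if (!is.data.frame(p$diagnosis_mix) ||
      !all(c("diagnosis", "count") %in% names(p$diagnosis_mix))) {
    fail("diagnosis_mix", "must be a data.frame with columns diagnosis, count")
  }
  if (any(p$diagnosis_mix$count < 0)) fail("diagnosis_mix", "has negative counts")
  if (sum(p$diagnosis_mix$count) != p$n_cases) {
    fail("diagnosis_mix", sprintf("counts sum to %d, not n_cases = %d",
                                  sum(p$diagnosis_mix$count), p$n_cases))
  }
  labs <- c("topical", "peribulbar", "subtenon", "retrobulbar", "general")
  if (!all(labs %in% names(p$anesthesia_mix))) {
    fail("anesthesia_mix", paste("must be named with", paste(labs, collapse = ", ")))
  }
  if (any(p$anesthesia_mix < 0)) fail("anesthesia_mix", "has negative counts")
  if (sum(p$anesthesia_mix) != p$n_cases) {
    fail("anesthesia_mix", sprintf("counts sum to %d, not n_cases = %d",
                                   sum(p$anesthesia_mix), p$n_cases))
  }
  if (p$n_patients + p$n_repeat_patients != p$n_cases) {
    fail("n_patients", "plus n_repeat_patients must equal n_cases (repeat patients own exactly two cases)")
  }
  if (p$n_repeat_patients > p$n_patients) fail("n_repeat_patients", "exceeds n_patients")
  if (p$n_surgeons < 1L) fail("n_surgeons", "must be at least 1")
  f <- p$technique_needle_fraction
  if (is.na(f) || f < 0 || f > 1) fail("technique_needle_fraction", "must lie in [0, 1]")
  if (p$n_general_misuse > p$n_general_term_total) {
    fail("n_general_misuse", "exceeds n_general_term_total")
  }
  if (p$n_no_hit_anesthesia + p$n_general_term_total > p$n_cases) {
    fail("n_no_hit_anesthesia", "plus n_general_term_total exceeds n_cases")
  }
  if (unname(p$anesthesia_mix["general"]) !=
      p$n_general_term_total - p$n_general_misuse) {
    fail("n_general_term_total",
         "minus n_general_misuse must equal anesthesia_mix['general'] (every true-general report says 'general')")
  }
  if (p$n_general_misuse > unname(p$anesthesia_mix["topical"])) {
    fail("n_general_misuse", "exceeds anesthesia_mix['topical'] (misuse cases are planted on topical cases)")
  }
  endo_dx <- p$diagnosis_mix$count[p$diagnosis_mix$diagnosis == "endophthalmitis"]
  endo_dx <- if (length(endo_dx)) sum(endo_dx) else 0L
  if (p$n_preexisting_endophthalmitis < endo_dx) {
    fail("n_preexisting_endophthalmitis",
         "is below the endophthalmitis count of diagnosis_mix (indication mentions are pre-existing mentions)")
  }
  ms <- p$mismatch_split
  if (!all(c("mrn_leading_zero", "dob_wrong", "name_misspelled") %in% names(ms))) {
    fail("mismatch_split", "must name mrn_leading_zero, dob_wrong, name_misspelled")
  }
  if (any(ms < 0) || sum(ms) != p$n_identifier_mismatches) {
    fail("mismatch_split", "must be non-negative and sum to n_identifier_mismatches")
  }
  fu <- p$followup
  for (nm in c("day1", "week", "month", "quarter")) {
    if (is.null(fu[[nm]]) || is.na(fu[[nm]]) || fu[[nm]] < 0L || fu[[nm]] > p$n_cases) {
      fail("followup", sprintf("count '%s' must lie in [0, n_cases]", nm))
    }
  }
  if (fu$week < fu$month || fu$month < fu$quarter) {
    fail("followup", "retention counts must be non-increasing across week, month, quarter windows")
  }
  if (p$n_cases - fu$week > 0L && fu$day1 > p$n_cases - 1L) {
    fail("followup", "day1 cannot cover every case when a case has no week-1 follow-up")
  }
  # specials (pre-existing endophthalmitis, complications, corrupted rows)
  # are planted on distinct single-case patients
  n_singles <- p$n_patients - p$n_repeat_patients
  n_special <- p$n_preexisting_endophthalmitis + p$n_true_complications +
    p$n_identifier_mismatches
  if (n_special > n_singles) {
    fail("n_identifier_mismatches",
         "plus n_preexisting_endophthalmitis and n_true_complications exceeds the number of single-case patients")
  }
  invisible(profile)
}

#' The packaged default cohort profile
#'
#' The study-cohort composition used throughout the package and its
#' acceptance checks: 1418 aqueous humor biopsies on 1154 patients by 17
#' surgeons; anesthesia counts topical 1021, peribulbar 125, subtenon 61,
#' retrobulbar 147, general 64 (so 211 cases under ocular muscle akinesia);
#' 50 operative reports with no usable anesthesia section; 104 reports
#' containing the word "general" of which 40 actually describe sedated local
#' anesthesia; 14 patients seen for endophthalmitis before the biopsy (six
#' of whom underwent surgery *for* endophthalmitis); exactly one true
#' complication (a small Descemet membrane tear); 14 manifest rows with a
#' data-entry identifier error; needle technique in 65.7% of cases; and a
#' follow-up schedule with 1408 day-1 visits, last-visit retention
#' 1377 / 1256 / 978 at the 1-week / 1-month / 3-month windows, median
#' last visit at day 223 and range 0-2003 days.
#'
#' @param seed integer seed stored in the profile (default 20240317).
#' @return a [cohort_profile()].
#' @examples
#' p <- default_profile()
#' p$n_cases
#' p$anesthesia_mix[["topical"]]
#' @export
default_profile <- function(seed = 20240317L) {
  cohort_profile(
    n_cases = 1418L,
    n_patients = 1154L,
    n_repeat_patients = 264L,
    n_surgeons = 17L,
    diagnosis_mix = study_diagnosis_mix(),
    anesthesia_mix = c(topical = 1021L, peribulbar = 125L, subtenon = 61L,
                       retrobulbar = 147L, general = 64L),
    technique_needle_fraction = 0.657,
    n_no_hit_anesthesia = 50L,
    n_general_term_total = 104L,
    n_general_misuse = 40L,
    n_preexisting_endophthalmitis = 14L,
    n_true_complications = 1L,
    n_identifier_mismatches = 14L,
    mismatch_split = c(mrn_leading_zero = 5L, dob_wrong = 5L,
                       name_misspelled = 4L),
    followup = list(day1 = 1408L, week = 1377L, month = 1256L, quarter = 978L,
                    median_day = 223L, max_day = 2003L),
    seed = seed)
}

# Primary surgical indications of the study cohort (counts sum to 1418).
study_diagnosis_mix <- function() {
  x <- c(
    "cataract" = 711L,
    "cataract, glaucoma" = 207L,
    "glaucoma" = 147L,
    "diabetic cataract" = 53L,
    "cataract, pseudoexfoliation" = 11L,
    "cataract, glaucoma, pseudoexfoliation" = 9L,
    "diabetic cataract, glaucoma" = 9L,
    "glaucoma, pseudoexfoliation" = 6L,
    "cataract, retinitis pigmentosa" = 4L,
    "cataract, proliferative diabetic retinopathy" = 3L,
    "trauma" = 3L,
    "uveitis, glaucoma" = 3L,
    "cataract, corneal edema" = 2L,
    "cataract, age-related macular degeneration" = 2L,
    "retained lens fragments" = 2L,
    "anterior segment-other" = 16L,
    "corneal edema" = 38L,
    "fuchs endothelial dystrophy" = 21L,
    "failed corneal transplant" = 15L,
    "corneal opacity" = 7L,
    "cornea-other" = 8L,
    "retinal detachment" = 24L,
    "epiretinal membrane" = 19L,
    "proliferative diabetic retinopathy" = 11L,
    "vitreous hemorrhage" = 9L,
    "macular hole" = 8L,
    "endophthalmitis" = 6L,
    "retinal detachment, vitreous hemorrhage" = 4L,
    "vitreous hemorrhage, proliferative diabetic retinopathy" = 4L,
    "retinitis pigmentosa" = 3L,
    "uveitis" = 3L,
    "autosomal dominant neovascular inflammatory vitreoretinopathy" = 3L,
    "macular hole, epiretinal membrane" = 2L,
    "usher syndrome" = 1L,
    "retina-other" = 22L,
    "uveal melanoma" = 20L,
    "vascular lesion" = 1L,
    "tumor/lesion-other" = 1L)
  data.frame(diagnosis = names(x), count = unname(x),
             stringsAsFactors = FALSE)
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("<cohort_profile> %d cases / %d patients / %d surgeons (seed %d)\n",
              x$n_cases, x$n_patients, x$n_surgeons, x$seed))
  cat("  anesthesia mix:",
      paste(sprintf("%s %d", names(x$anesthesia_mix), x$anesthesia_mix),
            collapse = ", "), "\n")
  cat(sprintf("  ambiguities: %d no-hit, %d 'general' (%d misuse); %d id mismatches\n",
              x$n_no_hit_anesthesia, x$n_general_term_total,
              x$n_general_misuse, x$n_identifier_mismatches))
  cat(sprintf("  planted: %d true complication(s), %d pre-existing endophthalmitis\n",
              x$n_true_complications, x$n_preexisting_endophthalmitis))
  invisible(x)
}
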