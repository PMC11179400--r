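#' Default text templates for the synthetic corpus
#'
#' Operative-report and clinical-note bodies are composed from these
#' templates. `{placeholders}` are substituted at generation time. The
#' templates are deliberately aligned with the flagging lexicon: every
#' complication phrase they mention in a non-complicated context is negated
#' with a cue from [default_term_lexicon()], and the affirmative
#' complication sentence avoids all cues. Users extending the term or cue
#' lexicons should extend these templates in step (pass a modified list to
#' [generate_corpus()] or edit a copy of
#' `system.file("extdata", "templates.yaml", package = "aqsafe")`).
#'
#' @return named list of template strings.
#' @export
corpus_templates <- function() {
  list(
    op_normal = paste(
      "operative report, {eye} eye.",
      "an anterior chamber paracentesis was performed at the start of the",
      "case and 50 to 100 microliters of aqueous humor was aspirated using",
      "a 30-gauge {instrument}.",
      "the anterior chamber remained deep and formed throughout.",
      "there was no lens touch, no iris touch, and no cornea touch.",
      "no bleeding, no hyphema, and no suprachoroidal hemorrhage were",
      "observed. the wound was watertight without leak.",
      "no descemet membrane tear was noted.",
      "the patient tolerated the procedure well without movement."),
    op_complication = paste(
      "operative report, {eye} eye.",
      "an anterior chamber paracentesis was performed at the start of the",
      "case and 50 to 100 microliters of aqueous humor was aspirated using",
      "a 30-gauge {instrument}.",
      "on withdrawal of aqueous there was shallowing of the anterior",
      "chamber, which was reinflated with balanced salt solution, at which",
      "time a small descemet membrane tear was noted adjacent to the",
      "paracentesis. the tear remained localized and small without",
      "extension.",
      "there was no lens touch, no iris touch, and no cornea touch.",
      "no bleeding, no hyphema, and no suprachoroidal hemorrhage were",
      "observed. the wound was watertight without leak.",
      "the patient tolerated the procedure well without movement."),
    op_endo_indication_prefix = paste(
      "indication: endophthalmitis, {eye} eye. pars plana vitrectomy with",
      "intravitreal antibiotics was performed."),
    adversarial_sentence = paste(
      "the tear film was stable and the wound was leak-free at the",
      "conclusion of the case."),
    note_followup = paste(
      "postoperative day {day} visit, {eye} eye.",
      "the eye is quiet and the vision is stable.",
      "cornea clear, anterior chamber deep and formed, no hyphema.",
      "the wound is seidel negative without leak.",
      "no signs of endophthalmitis."),
    note_preexisting_endo = paste(
      "patient seen in clinic for acute endophthalmitis of the {eye} eye.",
      "intravitreal antibiotics were administered and the infection is",
      "improving."),
    anesthesia_topical_a = "topical anesthesia with intracameral lidocaine was administered.",
    anesthesia_topical_b = "topical tetracaine drops were applied at the start of the case.",
    anesthesia_misuse = "transient general anesthesia with intravenous sedation; topical drops were applied.",
    anesthesia_peribulbar = "peribulbar block with 2% lidocaine and 0.75% bupivacaine.",
    anesthesia_subtenon = "subtenon anesthesia with lidocaine was administered.",
    anesthesia_retrobulbar = "retrobulbar block with lidocaine under monitored anesthesia care.",
    anesthesia_general = "general endotracheal anesthesia.",
    anesthesia_no_hit_text = "monitored anesthesia care.")
}

#' Read corpus templates from a YAML config file
#'
#' Fields missing from the file take the packaged defaults, so a config may
#' override a single template. The packaged default config is at
#' `system.file("extdata", "templates.yaml", package = "aqsafe")`.
#'
#' @param path YAML file path.
#' @return named template list, see [corpus_templates()].
#' @export
read_templates <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- corpus_templates()
  for (nm in intersect(names(raw), names(out))) out[[nm]] <- raw[[nm]]
  out
}

fill_template <- function(tpl, vals) {
  for (nm in names(vals)) {
    tpl <- gsub(paste0("\\{", nm, "\\}"), vals[[nm]], tpl)
  }
  tpl
}

.first_names <- c(
  "alma", "arthur", "beatrice", "carl", "clara", "daniel", "dora", "edwin",
  "elena", "felix", "frances", "george", "greta", "harold", "hazel", "irving",
  "iris_a", "james", "june", "karl", "laura", "louis", "mabel", "martin",
  "nina", "oscar", "pearl", "quentin", "rosa", "samuel", "sylvia", "theodore",
  "una", "victor", "wanda", "walter", "yolanda", "zachary", "norma", "hugo")

.surnames <- c(
  "abbott", "barnes", "calloway", "dempsey", "ellington", "fairbanks",
  "garrison", "holloway", "ingram", "jennings", "kowalski", "lindqvist",
  "mercer", "norwood", "ostrander", "pemberton", "quimby", "rutherford",
  "sandoval", "thackeray", "underhill", "vasquez", "whitfield", "yardley",
  "zimmerman", "ashworth", "blackwood", "crenshaw", "donnelly", "eastman",
  "fitzroy", "goldsmith", "hawthorne", "iverson", "jablonski", "kirkland",
  "lockhart", "montrose", "newberry", "ogilvie", "prescott", "ravenscroft",
  "stanfield", "tremaine", "vanderberg", "winslow")

# ---------------------------------------------------------------------------

#' Generate a synthetic biobank manifest and EHR document corpus
#'
#' Produces, deterministically from `profile$seed`, a biobank case manifest,
#' an EHR document set (one operative report per case dated on the procedure
#' date, plus dated clinical notes), and a machine-readable ground-truth
#' sidecar. All profile category counts are planted exactly: the anesthesia
#' mix, the no-hit and "general"-misuse reports, the pre-biopsy
#' endophthalmitis histories, the identifier corruptions (applied to the
#' manifest row; the EHR side keeps the true value), the affirmative
#' complication case(s), and the follow-up retention bands. Non-complicated
#' operative reports mention complication phrases only under negation.
#'
#' @param profile a [cohort_profile()].
#' @param templates template list, see [corpus_templates()].
#' @param adversarial if `TRUE`, a seeded 10% of non-complicated operative
#'   reports additionally receive a benign-homonym sentence ("tear film",
#'   "leak-free wound") that defeats naive term matching; off by default and
#'   excluded from any accuracy expectation.
#' @return an object of class `ehr_corpus`: list with `manifest`, `docs`,
#'   `truth` data.frames and the `profile`.
#' @examples
#' p <- cohort_profile(
#'   n_cases = 6, n_patients = 6, n_surgeons = 2,
#'   diagnosis_mix = data.frame(diagnosis = "cataract", count = 6),
#'   anesthesia_mix = c(topical = 4, peribulbar = 1, subtenon = 0,
#'                      retrobulbar = 1, general = 0),
#'   followup = list(day1 = 5, week = 5, month = 4, quarter = 2,
#'                   median_day = NA, max_day = 300),
#'   seed = 7)
#' corp <- generate_corpus(p)
#' nrow(corp$manifest)
#' @export
generate_corpus <- function(profile, templates = corpus_templates(),
                            adversarial = FALSE) {
  validate_profile(profile)
  p <- profile
  n <- p$n_cases
  if (n == 0L) {
    return(structure(list(manifest = empty_manifest(), docs = empty_docs(),
                          truth = empty_truth(), profile = p),
                     class = "ehr_corpus"))
  }
  old_seed <- get0(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(p$seed)

  # ---- patients ----
  n_pat <- p$n_patients
  n_rep <- p$n_repeat_patients
  first <- sample(.first_names, n_pat, replace = TRUE)
  last <- sample(.surnames, n_pat, replace = TRUE)
  pat_name <- paste(first, last)
  mrn_int <- sample.int(9999999L, n_pat)
  pat_dob <- as.Date("1930-01-01") + sample.int(27000L, n_pat, replace = TRUE)

  # ---- case -> patient (repeat patients 1..n_rep own two cases) ----
  pat_of_case <- c(seq_len(n_pat), seq_len(n_rep))
  is_second_case <- c(rep(FALSE, n_pat), rep(TRUE, n_rep))
  single_case <- pat_of_case > n_rep          # case of a single-case patient

  # ---- procedure dates and laterality ----
  proc_date <- as.Date("2018-01-01") + sample.int(1900L, n, replace = TRUE) - 1L
  lat <- sample(c("OD", "OS"), n, replace = TRUE)
  if (n_rep > 0L) {
    firsts <- seq_len(n_rep)                  # first case of repeat patients
    seconds <- n_pat + seq_len(n_rep)
    proc_date[seconds] <- proc_date[firsts] + sample(30:500, n_rep, replace = TRUE)
    lat[seconds] <- ifelse(lat[firsts] == "OD", "OS", "OD")
  }

  # ---- surgeons and technique (one technique per surgeon) ----
  n_needle <- round(p$technique_needle_fraction * n)
  if (n_needle > 0L && n_needle < n && p$n_surgeons < 2L) {
    stop("invalid cohort profile: field 'n_surgeons' must be at least 2 when both techniques are used",
         call. = FALSE)
  }
  n_sg_needle <- if (n_needle == 0L) 0L else if (n_needle == n) p$n_surgeons else
    max(1L, min(p$n_surgeons - 1L, round(p$technique_needle_fraction * p$n_surgeons)))
  surgeon_ids <- sprintf("S%02d", seq_len(p$n_surgeons))
  needle_cases <- sample.int(n, n_needle)
  technique <- rep("cannula", n)
  technique[needle_cases] <- "needle"
  surgeon <- character(n)
  if (n_sg_needle > 0L) {
    surgeon[technique == "needle"] <-
      sample(surgeon_ids[seq_len(n_sg_needle)], n_needle, replace = TRUE)
  }
  if (n_sg_needle < p$n_surgeons) {
    surgeon[technique == "cannula"] <-
      sample(surgeon_ids[(n_sg_needle + 1L):p$n_surgeons], n - n_needle,
             replace = TRUE)
  }

  # ---- diagnoses; endophthalmitis-indication cases moved onto single-case
  # patients so each patient's record carries mentions for one case only ----
  dx <- sample(rep(p$diagnosis_mix$diagnosis, p$diagnosis_mix$count))
  endo_idx <- which(dx == "endophthalmitis")
  for (i in endo_idx[!single_case[endo_idx]]) {
    cand <- which(single_case & dx != "endophthalmitis")
    j <- cand[1]
    tmp <- dx[i]; dx[i] <- dx[j]; dx[j] <- tmp
  }
  endo_idx <- which(dx == "endophthalmitis")

  # ---- special case sets, disjoint, on single-case patients ----
  pool <- shuffle(setdiff(which(single_case), endo_idx))
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  preexist_idx <- c(endo_idx,
                    take(p$n_preexisting_endophthalmitis - length(endo_idx)))
  compl_idx <- take(p$n_true_complications)
  corrupt_idx <- take(p$n_identifier_mismatches)
  corrupt_type <- rep(names(p$mismatch_split), p$mismatch_split)

  # ---- anesthesia truth and text phenomena ----
  anes_true <- sample(rep(names(p$anesthesia_mix), p$anesthesia_mix))
  # the complication case is reported under plain topical anesthesia
  if (length(compl_idx) && any(anes_true == "topical") &&
      anes_true[compl_idx[1]] != "topical") {
    j <- setdiff(which(anes_true == "topical"), compl_idx)[1]
    if (!is.na(j)) {
      anes_true[j] <- anes_true[compl_idx[1]]
      anes_true[compl_idx[1]] <- "topical"
    }
  }
  misuse_cand <- setdiff(which(anes_true == "topical"), compl_idx)
  if (length(misuse_cand) < p$n_general_misuse) {
    misuse_cand <- which(anes_true == "topical")
  }
  misuse_idx <- sample_exact(misuse_cand, p$n_general_misuse)
  nohit_cand <- setdiff(which(anes_true != "general"),
                        c(misuse_idx, compl_idx))
  if (length(nohit_cand) < p$n_no_hit_anesthesia) {
    nohit_cand <- setdiff(which(anes_true != "general"), misuse_idx)
  }
  nohit_idx <- sample_exact(nohit_cand, p$n_no_hit_anesthesia)

  # ---- follow-up schedule ----
  last_day <- shuffle(plant_last_visit_days(n, p$followup))
  no_day1 <- which(last_day == 0L)
  need <- (n - p$followup$day1) - length(no_day1)
  if (need > 0L) {
    cand <- which(last_day >= 2L)
    if (length(cand) < need) {
      # a last visit at day 1 *is* a day-1 visit; nudge enough such cases to
      # day 2 (same retention band) so the day-1 count can be planted
      ones <- which(last_day == 1L)
      promote <- ones[seq_len(need - length(cand))]
      last_day[promote] <- 2L
      cand <- which(last_day >= 2L)
    }
    no_day1 <- c(no_day1, sample_exact(cand, need))
  }
  has_day1 <- !(seq_len(n) %in% no_day1)
  followup_days <- lapply(seq_len(n), function(i) {
    if (last_day[i] == 0L) return(0L)
    mids <- c(7L, 30L, 90L)
    days <- c(if (has_day1[i]) 1L, mids[mids > 1L & mids < last_day[i]],
              last_day[i])
    sort(unique(as.integer(days)))
  })

  # ---- identifier corruption (manifest side; EHR keeps the truth) ----
  # MRN-corruption patients need a leading zero to drop
  mrn_targets <- corrupt_idx[corrupt_type == "mrn_leading_zero"]
  for (i in mrn_targets) {
    repeat {
      cand <- sample.int(999999L, 1L)
      if (!cand %in% mrn_int) break
    }
    mrn_int[pat_of_case[i]] <- cand
  }
  mrn_true <- sprintf("%07d", mrn_int)

  man_mrn <- mrn_true[pat_of_case]
  man_name <- pat_name[pat_of_case]
  man_dob <- pat_dob[pat_of_case]
  corruption <- rep("none", n)
  for (k in seq_along(corrupt_idx)) {
    i <- corrupt_idx[k]
    type <- corrupt_type[k]
    corruption[i] <- type
    if (type == "mrn_leading_zero") {
      man_mrn[i] <- sub("^0+", "", man_mrn[i])
    } else if (type == "dob_wrong") {
      man_dob[i] <- corrupt_dob(man_dob[i])
    } else {
      man_name[i] <- corrupt_name(man_name[i])
    }
  }

  # ---- manifest ----
  case_id <- sprintf("C%05d", seq_len(n))
  manifest <- data.frame(
    case_id = case_id,
    mrn = man_mrn,
    name = man_name,
    dob = man_dob,
    procedure_date = proc_date,
    laterality = lat,
    surgeon_id = surgeon,
    technique = technique,
    diagnosis = dx,
    stringsAsFactors = FALSE)

  # ---- texts ----
  eye_word <- ifelse(lat == "OD", "right", "left")
  instrument <- ifelse(technique == "needle", "needle", "blunt cannula")
  is_compl <- seq_len(n) %in% compl_idx
  body <- character(n)
  for (i in seq_len(n)) {
    tpl <- if (is_compl[i]) templates$op_complication else templates$op_normal
    b <- fill_template(tpl, list(eye = eye_word[i], instrument = instrument[i]))
    if (dx[i] == "endophthalmitis") {
      b <- paste(fill_template(templates$op_endo_indication_prefix,
                               list(eye = eye_word[i])), b)
    }
    body[i] <- b
  }
  if (adversarial) {
    adv_cand <- which(!is_compl)
    adv_idx <- sample_exact(adv_cand, max(1L, round(0.1 * length(adv_cand))))
    body[adv_idx] <- paste(body[adv_idx], templates$adversarial_sentence)
  }

  anes_text <- character(n)
  topical_variant <- sample(c(TRUE, FALSE), n, replace = TRUE)
  for (i in seq_len(n)) {
    anes_text[i] <-
      if (i %in% nohit_idx) {
        if (i %% 2L == 0L) "" else templates$anesthesia_no_hit_text
      } else if (i %in% misuse_idx) {
        templates$anesthesia_misuse
      } else {
        switch(anes_true[i],
               topical = if (topical_variant[i]) templates$anesthesia_topical_a
                         else templates$anesthesia_topical_b,
               peribulbar = templates$anesthesia_peribulbar,
               subtenon = templates$anesthesia_subtenon,
               retrobulbar = templates$anesthesia_retrobulbar,
               general = templates$anesthesia_general)
      }
  }

  # ---- documents ----
  op_docs <- data.frame(
    doc_id = sprintf("%s-OP", case_id),
    case_id = case_id,
    mrn = mrn_true[pat_of_case],
    name = pat_name[pat_of_case],
    dob = pat_dob[pat_of_case],
    kind = "operative_report",
    date = proc_date,
    anesthesia_text = anes_text,
    body = body,
    stringsAsFactors = FALSE)

  n_notes <- lengths(followup_days)
  note_case <- rep(seq_len(n), n_notes)
  note_day <- unlist(followup_days)
  note_docs <- NULL
  if (length(note_case)) {
    note_docs <- data.frame(
      doc_id = sprintf("%s-N%02d", case_id[note_case], sequence(n_notes)),
      case_id = case_id[note_case],
      mrn = mrn_true[pat_of_case[note_case]],
      name = pat_name[pat_of_case[note_case]],
      dob = pat_dob[pat_of_case[note_case]],
      kind = "clinical_note",
      date = proc_date[note_case] + note_day,
      anesthesia_text = "",
      body = vapply(seq_along(note_case), function(r) {
        fill_template(templates$note_followup,
                      list(day = note_day[r], eye = eye_word[note_case[r]]))
      }, character(1)),
      stringsAsFactors = FALSE)
  }

  endo_docs <- NULL
  if (length(preexist_idx)) {
    prior_offset <- sample(60:2500, length(preexist_idx), replace = TRUE)
    endo_docs <- data.frame(
      doc_id = sprintf("%s-E01", case_id[preexist_idx]),
      case_id = case_id[preexist_idx],
      mrn = mrn_true[pat_of_case[preexist_idx]],
      name = pat_name[pat_of_case[preexist_idx]],
      dob = pat_dob[pat_of_case[preexist_idx]],
      kind = "clinical_note",
      date = proc_date[preexist_idx] - prior_offset,
      anesthesia_text = "",
      body = vapply(preexist_idx, function(i) {
        fill_template(templates$note_preexisting_endo,
                      list(eye = eye_word[i]))
      }, character(1)),
      stringsAsFactors = FALSE)
  }

  docs <- rbind(op_docs, note_docs, endo_docs)
  docs <- docs[order(docs$case_id, docs$date, docs$doc_id), , drop = FALSE]
  rownames(docs) <- NULL

  # ---- ground truth sidecar ----
  truth <- data.frame(
    case_id = case_id,
    anesthesia_true = anes_true,
    anesthesia_section_present = nzchar(anes_text),
    general_misuse = seq_len(n) %in% misuse_idx,
    complications_true = ifelse(is_compl, "tear", ""),
    has_preexisting_endophthalmitis = seq_len(n) %in% preexist_idx,
    identifier_corruption = corruption,
    last_visit_day = last_day,
    stringsAsFactors = FALSE)
  truth$followup_days <- I(followup_days)

  structure(list(manifest = manifest, docs = docs, truth = truth,
                 profile = p),
            class = "ehr_corpus")
}

# length-safe shuffle (sample() would expand a length-1 integer)
shuffle <- function(x) x[sample.int(length(x))]

# sample k elements from x without the size-1 surprise of sample()
sample_exact <- function(x, k) {
  if (k == 0L) return(integer(0))
  if (length(x) < k) {
    stop(sprintf("cannot plant %d cases in a candidate pool of %d", k,
                 length(x)), call. = FALSE)
  }
  x[sample.int(length(x), k)]
}

corrupt_dob <- function(d) {
  lt <- as.POSIXlt(d)
  day <- lt$mday
  mon <- lt$mon + 1L
  if (day <= 12L && day != mon) {
    # transpose month and day
    as.Date(sprintf("%04d-%02d-%02d", lt$year + 1900L, day, mon))
  } else {
    as.Date(d) + if (day < 28L) 1L else -1L
  }
}

corrupt_name <- function(nm) {
  ch <- strsplit(nm, "")[[1]]
  alpha <- which(grepl("[a-z]", ch))
  i <- alpha[sample.int(length(alpha), 1L)]
  repeat {
    repl <- sample(letters, 1L)
    if (repl != ch[i]) break
  }
  ch[i] <- repl
  paste(ch, collapse = "")
}

# last-visit day offsets hitting the retention band counts exactly; the
# median and maximum are forced by construction when the bands allow it
plant_last_visit_days <- function(n, fu) {
  k0 <- n - fu$week
  k7 <- fu$week - fu$month
  k30 <- fu$month - fu$quarter
  k90 <- fu$quarter
  max_day <- if (is.null(fu$max_day) || is.na(fu$max_day)) 400L else
    as.integer(fu$max_day)
  med <- if (is.null(fu$median_day)) NA_integer_ else as.integer(fu$median_day)
  b0 <- if (k0 > 0L) c(0L, sample_band(1L, 6L, k0 - 1L)) else integer(0)
  b7 <- sample_band(7L, 29L, k7)
  b30 <- sample_band(30L, 89L, k30)
  b90 <- integer(0)
  if (k90 > 0L) {
    forced <- FALSE
    if (!is.na(med)) {
      lr <- (n + 1L) %/% 2L
      ur <- n %/% 2L + 1L
      pos_l <- lr - (n - k90)
      pos_u <- ur - (n - k90)
      low_n <- pos_l - 1L
      high_n <- k90 - low_n - (pos_u - pos_l + 1L) - 1L
      if (pos_l >= 1L && pos_u <= k90 && med >= 90L && med < max_day &&
          high_n >= 0L && (low_n == 0L || med > 90L)) {
        b90 <- c(sample_band(90L, med - 1L, low_n),
                 rep(med, pos_u - pos_l + 1L),
                 sample_band(med, max_day - 1L, high_n),
                 max_day)
        forced <- TRUE
      }
    }
    if (!forced) {
      b90 <- c(sample_band(90L, max_day, k90 - 1L), max_day)
    }
  }
  c(b0, b7, b30, b90)
}

sample_band <- function(lo, hi, k) {
  if (k <= 0L) return(integer(0))
  if (hi < lo) hi <- lo
  sample(seq.int(lo, hi), k, replace = TRUE)
}

empty_manifest <- function() {
  data.frame(case_id = character(0), mrn = character(0), name = character(0),
             dob = as.Date(character(0)),
             procedure_date = as.Date(character(0)),
             laterality = character(0), surgeon_id = character(0),
             technique = character(0), diagnosis = character(0),
             stringsAsFactors = FALSE)
}

empty_docs <- function() {
  data.frame(doc_id = character(0), case_id = character(0), mrn = character(0),
             name = character(0), dob = as.Date(character(0)),
             kind = character(0), date = as.Date(character(0)),
             anesthesia_text = character(0), body = character(0),
             stringsAsFactors = FALSE)
}

empty_truth <- function() {
  out <- data.frame(case_id = character(0), anesthesia_true = character(0),
                    anesthesia_section_present = logical(0),
                    general_misuse = logical(0),
                    complications_true = character(0),
                    has_preexisting_endophthalmitis = logical(0),
                    identifier_corruption = character(0),
                    last_visit_day = integer(0), stringsAsFactors = FALSE)
  out$followup_days <- I(list())
  out
}

#' @export
print.ehr_corpus <- function(x, ...) {
  cat(sprintf("<ehr_corpus> %d cases, %d documents (seed %d)\n",
              nrow(x$manifest), nrow(x$docs), x$profile$seed))
  invisible(x)
}
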