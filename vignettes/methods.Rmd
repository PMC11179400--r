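---
title: "Free-text EHR surveillance of aqueous humor biopsy safety: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-text EHR surveillance of aqueous humor biopsy safety: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqsafe)
```

## The surveillance problem

Aqueous humor (AH) liquid biopsies -- withdrawing 50--100 µL of anterior
chamber fluid through a paracentesis at the start of intraocular surgery --
enable proteomic, metabolomic and genomic analyses in living patients. Before
such sampling can be recommended at scale, its own complication profile must
be separated from that of the host surgery. The evidence lives in free text:
operative reports and postoperative clinical notes written by many surgeons in
their own words. Manual chart review does not scale to four-digit cohorts, and
billing codes under-capture intraoperative events, so the practical instrument
is a rule-based free-text search with negation handling, followed by manual
review of a bounded set of flagged or ambiguous cases.

`aqsafe` implements that instrument as a tested pipeline, and pairs it with a
synthetic EHR corpus generator so that every stage can be validated against
planted ground truth without access to any protected health information.

## The pipeline

Stages run in a fixed order (see `run_pipeline()`):

1. **Linkage** (`link_corpus()`): each biobank manifest row is matched to the
   EHR side on MRN, normalized name and date of birth, requiring an operative
   report dated on the procedure date.
2. **Complication flagging** (`flag_corpus()`): every occurrence of each of
   the twelve complication phrases ("lens touch", "iris touch", "cornea
   touch", "bleeding", "hemorrhage", "hyphema", "tear", "leak", "shallow",
   "movement", "suprachoroidal", "endophthalmitis") is located in the
   operative report and all clinical notes; a per-case flag is raised iff a
   non-negated mention exists. Evidence spans and sentence excerpts are kept
   for review.
3. **Anesthesia classification** (`classify_anesthesia()`): a word-boundary
   term search over the anesthesia section of the operative report, mapped to
   a final label by a fixed rule table with a no-hit pathway and a
   "general"-misuse rule.
4. **Temporal adjudication** (`classify_endophthalmitis()`): endophthalmitis
   mentions are pre-existing unless dated strictly after the procedure.
5. **Follow-up** (`followup_summary()`): visit-day arithmetic and retention.
6. **Safety report and audit** (`complication_report()`, `run_audit()`):
   rates with exact intervals, and a seeded random-sample re-review.

## Negation model

The matcher follows the NegEx convention. Text is normalized (lowercase,
ASCII punctuation, collapsed whitespace); mention spans are 0-based,
half-open offsets into the normalized text. Tokens are maximal runs of
non-space, non-punctuation characters, with `.`, `;`, `:` and `,` as
single-character tokens. A mention is negated when a pre-position cue
(defaults: *no, not, without, denies, denied, negative for, free of, absent,
(-)*) lies wholly within the 5 tokens before the phrase, or a post-position
cue (*was not seen, were not seen, not noted, ruled out*) within the 5
tokens after it, with no scope terminator (*but, however, although, though,
yet*, or sentence punctuation) between cue and phrase. Phrases match at word
boundaries only, longest phrase first, so a user-extended lexicon containing
both "lens touch" and "touch" never double-counts.

Deliberate consequences of these choices:

* **No stemming.** "tears" does not match "tear", and "shallowing" does not
  match "shallow". The term list is a fixed, surgeon-derived vocabulary; an
  inflection toggle would change the operating point silently, so none is
  applied by default.
* **Commas do not end negation scope** ("no bleeding, no hyphema" negates
  both), but sentence punctuation does: "wound was watertight. tear of
  descemet membrane" leaves the tear mention affirmative.
* The matcher is validated against a brute-force scope oracle on an
  enumerated grammar of more than 1000 cue × filler × term × tail strings
  (see `tests/testthat/`).

```{r negation}
find_mentions("no bleeding, no hyphema, chamber remained deep")
find_mentions("a small descemet membrane tear was noted")
```

## Anesthesia rules

Only the anesthesia section is searched automatically; recovering a type
documented elsewhere in the report is, by design, a review action. The rule
table: a matched block term wins by depth (retrobulbar > peribulbar >
subtenon > topical), `intracameral` and `lidocaine` are adjuncts of topical
and cannot decide a label alone (they refer the case to review), no matched
term is a *no-hit*, and a matched `general` is inspected for misuse --
"general" within three tokens after "transient", or co-occurrence with
intravenous-sedation phrasing plus a local term -- in which case the
accompanying local term supplies the label and the case is referred to
review. Retrobulbar and general anesthesia imply ocular muscle akinesia.

Two accuracy readings are reported because the denominator convention is a
genuine choice: `auto_accuracy` scores every case by its automatic label
(no-hit cases, whose label is `unknown`, count as errors), while
`auto_accuracy_strict` also counts every review-flagged case as manual work.
On the default cohort these are 96.5% and 93.7%; misclassification outside
the review pathway is zero, which is the property the workflow depends on.

## Record linkage

Biobank manifests are typed by hand in the operating room, so a small number
of rows carry entry errors. The linker requires agreement on at least two of
the three identifiers *plus* a same-date operative report, and the
disagreeing field must be explainable by a known corruption: an MRN equal in
value but shorter by up to two (dropped leading zeros), a DOB with
month/day transposed or a single field edited, or a name within edit
distance 2. This is the weakest rule that uniquely resolves all three
corruption types; anything else -- including two candidates that both
satisfy the rule -- stays `unresolved` and aborts a strict pipeline run.
The generator and the linker share this corruption taxonomy, and a property
test asserts that planted corruption is always recoverable.

## Temporal adjudication and follow-up

Endophthalmitis is both a surgical indication and the key postoperative
safety outcome, so the raw term flag is never reported directly: a case is
`postoperative` only if a non-negated mention sits in a document dated
strictly after the procedure date. Operative-report mentions (dated on the
procedure day) are pre/peri-operative by definition.

"Followed-up for W" is read as *last visit at day ≥ W* (the default), with
the *any visit in [1, W]* reading computed alongside, since either is
defensible; day-1 retention specifically means a visit at offset 1. One
month is 30 days and three months 90 days -- documented constants, not
attempts at calendar arithmetic.

## Rates, intervals, audit

Complication rates use Clopper--Pearson exact intervals
(`clopper_pearson()`, beta-quantile form, α = 0.05), the appropriate choice
for 0- and 1-event counts; the implementation is cross-checked against the
exact-test interval of `stats::binom.test()` to 10⁻⁶ and its empirical
coverage is exercised at p = 0.001, n = 1418. Displayed rates below 1% use
two significant figures (hence 1/1418 prints as 0.07%). The audit draws a
seeded uniform sample without replacement (default fraction 500/1418) and
scores each sampled case's complete flag set against the reviewer table.

## The synthetic cohort: what it emulates, and what it does not

`default_profile()` encodes the study-cohort composition: 1418 cases on
1154 patients (264 patients contribute two cases -- the split between
bilateral and repeat cases is not documented, so exactly-two repeats is an
assumption, not a claim) by 17 surgeons; final anesthesia labels topical
1021 / peribulbar 125 / subtenon 61 / retrobulbar 147 / general 64; 50
reports with an empty or uninformative ("monitored anesthesia care")
anesthesia section; 104 reports containing "general", 40 of them
"transient general anesthesia" with intravenous sedation over a topical
case; 14 patients seen for endophthalmitis before the biopsy (including the
6 operated *for* endophthalmitis); one affirmative Descemet membrane tear;
14 corrupted manifest rows (5 dropped-zero MRNs, 5 wrong DOBs, 4 misspelled
names -- an even split is assumed, the study does not break the 14 down);
needle technique in 65.7% of cases; and a follow-up schedule with 1408
day-1 visits, last-visit retention 1377/1256/978 at 7/30/90 days, median
223 days, range 0--2003.

Category counts are **planted exactly rather than sampled** from
proportions: the study reports exact counts, and planting makes every
corpus-level tally a deterministic function of the profile, independent of
the seed. The seed still drives names, dates, identifiers, assignment of
phenomena to cases and the within-band follow-up days; the last-visit
distribution forces the published minimum, maximum and median by
construction and samples the remaining days uniformly within retention
bands (real follow-up is right-skewed with visit clustering; nothing
downstream depends on the shape).

Note text is template-composed (templates are configurable alongside the
term lexicon, so extending one can extend the other in step). The templates
guarantee that non-complicated reports mention complication phrases only
under lexicon cues, and that planted complications avoid all cues -- a
self-consistency the test suite checks by running the flagger over clean
corpora. Real notes are messier: misspellings, copy-forward text, benign
homonyms ("tear film", "leak-free wound"). The optional `adversarial`
generator flag injects such homonyms to quantify that failure mode, and no
accuracy claim is made for it. Passing tests on the synthetic corpus
therefore demonstrate that the *algorithmic* pipeline is faithful -- exact
recovery of planted truth, sound negation scope, recoverable linkage -- not
that the lexicon generalizes to another institution's prose.

## Numerical and degenerate-input choices

* All dates are ISO-8601; undated documents are an error wherever dates
  carry meaning (temporal adjudication, follow-up).
* Serialization is byte-stable: identical `(profile, seed)` pairs produce
  identical files, which the suite asserts literally.
* An empty cohort is a valid generator input (empty outputs) but an invalid
  pipeline input; profile validation errors always name the offending
  field.
* A case whose last follow-up falls on day 1 necessarily has a day-1 visit;
  when the planted day-1 count requires more absentees than the schedule
  allows, the generator nudges such cases to day 2 within the same
  retention band.
* `run_audit()` restores the caller's RNG state; pipeline determinism never
  leaks into or out of user code.

## Problem sizes

The default cohort (1418 cases, ~7,800 documents, ~33,000 term mentions)
runs end to end in a few seconds; the test suite, including the full-cohort
acceptance checks, the 1000-string negation grammar and 100-profile
property sweeps, completes in well under a minute. Property suites use
miniature cohorts (14--50 cases) because every planted phenomenon scales
down without loss.

## Known limitations

* The lexicons are the study's verbatim term lists; they are configuration,
  not a general ophthalmic NER system. No UMLS/SNOMED mapping, no spelling
  correction, no machine learning.
* Linkage is deterministic rule-based matching, not probabilistic
  (Fellegi--Sunter) linkage; it resolves the documented corruption types
  and nothing more.
* Retention has no censoring adjustment; it is descriptive arithmetic, as
  in the source workflow.
* The generator does not model inter-surgeon language variation beyond the
  template set; coverage claims about new report styles require extending
  the templates and lexicon together.
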