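# aqsafe

Rule-based free-text surveillance of electronic health records (EHR) to
establish the safety of anterior-chamber (aqueous humor) liquid biopsies.

Aqueous humor sampling at the start of intraocular surgery enables
proteomic, metabolomic and genomic analyses in living patients, but its
complication profile must be separated from that of the host surgery — and
the evidence sits in free text written by many surgeons. `aqsafe` is for
clinical informaticians and surgical-outcomes researchers who need that
review to be reproducible: it implements negation-aware complication
flagging over operative reports and clinical notes, anesthesia-type
classification with explicit review pathways, biobank-to-EHR record
linkage tolerant of data-entry errors, temporal adjudication of
endophthalmitis mentions, follow-up retention arithmetic, and exact
interval estimates of complication rates — together with a seeded
synthetic EHR corpus generator with planted ground truth, so the whole
pipeline is testable without any protected health information.

## The method in brief

For each case *i* with procedure date *d(i)*, the flagger searches the
operative report and all clinical notes for a fixed phrase list
("lens touch", "iris touch", "cornea touch", "bleeding", "hemorrhage",
"hyphema", "tear", "leak", "shallow", "movement", "suprachoroidal",
"endophthalmitis"). A mention is **negated** iff a pre-cue (e.g. *no*,
*without*, *negative for*) occurs within 5 tokens before it — or a
post-cue (*was not seen*, *not noted*, …) within 5 tokens after — with no
scope terminator (*but*, *however*, `.` `;` `:`) in between (the NegEx
convention). The flag for term *t* is

&nbsp;&nbsp;&nbsp;&nbsp;flag(i, t) = 1 iff at least one non-negated mention of *t* exists in case *i*'s documents.

Endophthalmitis flags are then adjudicated temporally (postoperative iff a
non-negated mention is dated strictly after *d(i)*), and each
complication count *x* out of *n* cases is reported as a percentage with a
Clopper–Pearson exact 95% interval,
lower = Beta(α/2; x, n−x+1), upper = Beta(1−α/2; x+1, n−x).
A seeded uniform audit sample (fraction 500/1418 by default) re-scores the
flags against a reviewer table.

## Worked example

```r
library(aqsafe)

res <- run_pipeline(seed = 1)   # packaged 1418-case default cohort
res$report
#> <safety_report> n = 1418 cases
#>   total complications: 1 (0.07%), 95% CI [0.002%, 0.392%]
#>   postoperative endophthalmitis: 0
#>   Descemet membrane tear: 1 (0.07%)

res$audit
#> <audit_result> 500 cases audited (35.3% of cohort)
#>   complication-flag accuracy: 100.0% (intraoperative terms: 100.0%)

res$anesthesia$n_no_hit          # reports with no usable anesthesia section
#> [1] 50
res$anesthesia$akinesia_count    # retrobulbar or general anesthesia
#> [1] 211
res$followup$retention[, c("window", "days", "last_visit_count", "last_visit_fraction")]
#>    window days last_visit_count last_visit_fraction
#> 1    week    7             1377           0.9710860
#> 2   month   30             1256           0.8857546
#> 3 quarter   90              978           0.6897038
```

Reading: on the synthetic default cohort (1418 biopsies, ground truth
planted to mirror the study cohort), the pipeline flags exactly one
biopsy-related complication — a small Descemet membrane tear, 0.07% with
an exact upper bound below 0.4% — finds no postoperative endophthalmitis
among 14 raw term hits (all pre-existing disease), classifies anesthesia
automatically in 96.5% of cases with every error confined to the manual
review pathway, and reproduces the follow-up retention table (97.1% at one
week) from visit-date arithmetic.

The same workflow is broken into narrative stages under `analysis/`
(`01_build_cohort.R` … `06_safety_report.R`), each writing its tables
under `results/`. The negation matcher is also available directly:

```r
find_mentions("no bleeding, no hyphema, chamber remained deep")
#>       term start end negated                                        excerpt
#> 1 bleeding     3  11    TRUE no bleeding, no hyphema, chamber remained deep
#> 2  hyphema    16  23    TRUE no bleeding, no hyphema, chamber remained deep
```

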