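#!/usr/bin/env Rscript
# Adjudicate every endophthalmitis mention against the biopsy date
# (pre-existing disease vs a true postoperative event) and compute the
# follow-up retention table from visit-date arithmetic.

suppressPackageStartupMessages(library(aqsafe))

manifest <- read_manifest("results/corpus/manifest.csv")
docs <- read_docs("results/corpus/docs.jsonl")

flagged <- flag_corpus(manifest, docs)
tmp <- endophthalmitis_temporal(manifest, flagged$mentions)
out <- tmp
out$earliest_mention_date <- as.character(out$earliest_mention_date)
write.csv(out, "results/temporal.csv", row.names = FALSE)

cat(sprintf("endophthalmitis term hits: %d case(s); pre-existing only: %d; postoperative: %d\n",
            sum(tmp$classification != "none"),
            sum(tmp$classification == "preexisting_only"),
            sum(tmp$classification == "postoperative")))

fs <- followup_summary(manifest, docs)
jsonlite::write_json(
  list(day1_count = fs$day1_count, day1_fraction = fs$day1_fraction,
       retention = fs$retention, median_day = fs$median_day,
       min_day = fs$min_day, max_day = fs$max_day),
  "results/followup.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("day-1 follow-up: %d (%.1f%%)\n", fs$day1_count,
            100 * fs$day1_fraction))
print(fs$retention)
cat(sprintf("median follow-up %d days (range %d-%d)\n",
            fs$median_day, fs$min_day, fs$max_day))
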