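#!/usr/bin/env Rscript
# Classify the anesthesia type of every case from the operative report's
# anesthesia section, then apply review resolutions (from the ground-truth
# sidecar, standing in for manual review) to no-hit and "general"-misuse
# cases.

suppressPackageStartupMessages(library(aqsafe))

manifest <- read_manifest("results/corpus/manifest.csv")
docs <- read_docs("results/corpus/docs.jsonl")
truth <- read_truth("results/corpus/truth.jsonl")

calls <- classify_corpus_anesthesia(manifest, docs)
review <- calls$needs_review | calls$no_hit
resolutions <- data.frame(
  case_id = calls$case_id[review],
  final_label = truth$anesthesia_true[match(calls$case_id[review],
                                            truth$case_id)])
s <- summarize_anesthesia(calls, resolutions)
write.csv(s$cases, "results/anesthesia_calls.csv", row.names = FALSE)

n <- s$n
cat("final anesthesia labels:\n")
print(s$label_counts)
cat(sprintf("no-hit: %d (%.1f%%); 'general' matched: %d (%.1f%%), of which %d (%.1f%%) resolved to a local type\n",
            s$n_no_hit, 100 * s$no_hit_fraction,
            s$n_general_term, 100 * s$n_general_term / n,
            s$n_general_resolved_local,
            100 * s$n_general_resolved_local / n))
cat(sprintf("automatic accuracy: %.1f%% (strict reading, review cases counted as manual work: %.1f%%)\n",
            100 * s$auto_accuracy, 100 * s$auto_accuracy_strict))
cat(sprintf("ocular muscle akinesia: %d cases (%.1f%%)\n",
            s$akinesia_count, 100 * s$akinesia_fraction))
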