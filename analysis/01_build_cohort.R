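#!/usr/bin/env Rscript
# Build the synthetic study cohort: 1418 aqueous humor biopsies on 1154
# patients, with the documented anesthesia ambiguities, identifier entry
# errors, pre-biopsy endophthalmitis histories, one Descemet tear and the
# follow-up schedule all planted. Writes the manifest, the EHR documents
# and the ground-truth sidecar under results/corpus/.

suppressPackageStartupMessages(library(aqsafe))

profile <- default_profile()
corpus <- generate_corpus(profile)
write_corpus(corpus, "results/corpus")

cat(sprintf("cohort: %d cases, %d patients, %d documents\n",
            nrow(corpus$manifest), length(unique(corpus$docs$mrn)),
            nrow(corpus$docs)))
print(profile)
cat("wrote results/corpus/{manifest.csv,docs.jsonl,truth.jsonl}\n")
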