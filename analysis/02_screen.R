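#!/usr/bin/env Rscript
# Stage 2 -- artifact screening and within-stratum dereplication.
#
# Flags organellar fragments and tandem-repeat circularization artifacts,
# then collapses near-identical elements within each contamination stratum
# (the synthetic survey carries no sequences, so dereplication falls back to
# the rotation-canonical annotation fingerprint).

library(metamobilome)

vocab <- load_vocabulary()
elements <- read_annotation_table("results/data/annotations.tsv")

scr <- screen_elements(elements, vocab)
write.table(scr$report, "results/screen_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("input elements:  ", length(elements), "\n")
cat("removed:         ", sum(scr$report$removed), "\n")
print(table(scr$report$reason))
cat("representatives: ", length(scr$representatives), "\n")
cat("written: results/screen_report.tsv\n")
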