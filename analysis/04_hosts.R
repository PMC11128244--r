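#!/usr/bin/env Rscript
# Stage 4 -- host prediction.
#
# Non-viral elements: gene-taxonomy majority vote (a phylum is called iff
# >50% of all CDS agree). Viral elements: k-mer host predictions from the
# evidence table; CRISPR-spacer hits filtered to <= 1 mismatch give
# finer-grained calls where available.

library(metamobilome)

vocab <- load_vocabulary()
elements <- read_annotation_table("results/data/annotations.tsv")
evidence <- read_evidence_table("results/data/evidence.tsv")
report <- read.delim("results/screen_report.tsv")
surv <- elements[report$element_id[!report$removed]]
classes <- read.delim("results/classes.tsv")

calls <- host_calls(surv, classes, evidence = evidence)
summ <- host_summary(surv, classes, evidence)
write.table(calls, "results/host_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summ, "results/host_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

crispr <- lapply(evidence, crispr_host)
cat("non-viral elements voted:", nrow(calls), "\n")
cat("unassigned fraction:",
    sprintf("%.2f", mean(calls$taxon == "unassigned")), "\n")
cat("viral elements with filtered CRISPR host:",
    sum(lengths(crispr) > 0), "\n")
print(summ[summ$group == "non_viral" & summ$taxon != "unassigned", ])
cat("written: results/host_calls.tsv, results/host_summary.tsv\n")
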