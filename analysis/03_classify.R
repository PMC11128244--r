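#!/usr/bin/env Rscript
# Stage 3 -- four-tier classification cascade.
#
# viral (confident viral category) -> plasmid (database hit within mash
# thresholds) -> unclassified MGE (MGE Pfam; then extended-library domains)
# -> cryptic. Labels are checked against the generator's ground truth.

library(metamobilome)

vocab <- load_vocabulary()
elements <- read_annotation_table("results/data/annotations.tsv")
evidence <- read_evidence_table("results/data/evidence.tsv")
report <- read.delim("results/screen_report.tsv")
surv <- elements[report$element_id[!report$removed]]

classes <- classify_elements(surv, evidence, vocab)
summ <- summarize_classes(classes, surv)
write.table(classes, "results/classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summ, "results/class_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read_ground_truth("results/data/ground_truth.json")
lab <- setNames(classes$label, classes$element_id)
common <- intersect(truth$element_id, names(lab))
cat("class recovery vs ground truth:",
    sprintf("%.1f%%", 100 * mean(lab[common] ==
      setNames(truth$true_class, truth$element_id)[common])), "\n")
print(summ)
cat("written: results/classes.tsv, results/class_summary.tsv\n")
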