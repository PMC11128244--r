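#!/usr/bin/env Rscript
# Stage 5 -- heavy-metal-resistance-gene statistics.
#
# HMRG screening against the curated COG list; per-Mbp and per-CDS densities
# by stratum; per-gene Fisher-exact enrichment with BH correction; the
# +/-4-ORF circular neighborhood statistic; co-occurrence matrix; element
# size statistics (Welch test); association with conjugative elements; AMG
# candidates on viral elements.

library(metamobilome)

vocab <- load_vocabulary()
elements <- read_annotation_table("results/data/annotations.tsv")
report <- read.delim("results/screen_report.tsv")
surv <- elements[report$element_id[!report$removed]]
classes <- read.delim("results/classes.tsv")
lab <- setNames(classes$label, classes$element_id)

hits <- screen_genes(surv, vocab, "HMRG")
dens <- stratum_density(surv, hits)
write.table(dens, "results/densities.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("HMRG density (per Mbp):\n"); print(dens[, c("stratum", "per_mbp")])

enr <- enrichment_table(surv, vocab, "HMRG")
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("HMRG COGs at q < 0.05:", sum(enr$q < 0.05), "of", nrow(enr), "\n")

st <- element_strata(surv)
adj <- vapply(c("high_U", "low_U"), function(s)
  suppressWarnings(adjacency_probability(surv[st == s], vocab)), numeric(1))
cat(sprintf("adjacency probability (+/-4 ORFs): high %.3f, low %.3f\n",
            adj[1], adj[2]))

cooc <- cooccurrence_matrix(surv, vocab)
write.table(cooc, "results/cooccurrence.tsv", sep = "\t", quote = FALSE,
            col.names = NA)

sz <- size_stats(surv)
cat(sprintf("mean length: high %.0f bp, low %.0f bp (Welch p = %.2g)\n",
            sz$by_stratum$mean_length[sz$by_stratum$stratum == "high_U"],
            sz$by_stratum$mean_length[sz$by_stratum$stratum == "low_U"],
            sz$welch$p))

nonviral <- surv[lab[names(surv)] != "viral"]
assoc <- hmrg_conjugation_association(nonviral, vocab, classes)
cat(sprintf("HMRG genes on conjugative elements: %.1f%% (Fisher p = %.3g)\n",
            100 * assoc$fraction_hmrg_on_conjugative, assoc$p))

amgs <- identify_amgs(surv[lab[names(surv)] == "viral"], vocab)
write.table(amgs, "results/amgs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("AMG candidates on viral elements:", nrow(amgs),
    "| metal-related:", sum(amgs$metal_related), "\n")
cat("written: densities, enrichment, cooccurrence, amgs TSVs under results/\n")
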