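#!/usr/bin/env Rscript
# Stage 4: oxalotrophy toolkit calls.
#
# Classifies each strain by completeness of the biomineralization
# (Oxc + Frc + OxlT) and assimilation (Gcl + hydroxypyruvate reductase +
# serine-glyoxylate transaminase) toolkits and tabulates the Venn-style
# overlaps for Pseudomonas versus the other genera.

suppressPackageStartupMessages(library(oxascreen))

cohort <- read_cohort("results/cohort/proteomes", "results/cohort/metadata.tsv")
cn_tab <- read.delim("results/profile/copy_number.tsv", check.names = FALSE)
cn <- as.matrix(cn_tab[, -1])
rownames(cn) <- cn_tab$strain_id
class(cn) <- c("trait_matrix", class(cn))

calls <- classify_cohort(cn)
dir.create("results/toolkits", recursive = TRUE, showWarnings = FALSE)
write.table(calls, "results/toolkits/toolkit_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
oc <- overlap_counts(calls, genus_grouping(cohort, "Pseudomonas"))
write.table(oc, "results/toolkits/overlap_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(oc, "results/toolkits/overlap_counts.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

for (i in seq_len(nrow(oc)))
  message(oc$group_label[i], ": ", oc$n_strains[i], " strains — both ",
          oc$n_both[i], ", biomineralization-only ", oc$n_biomin_only[i],
          ", assimilation-only ", oc$n_assim_only[i], ", neither ",
          oc$n_neither[i])
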