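#!/usr/bin/env Rscript
# Stage 3: trait matrices and genus profiles.
#
# Builds the copy-number and presence/absence matrices from the filtered
# hits, summarises enzyme occurrence per genus, clusters classes by
# prevalence (ubiquitous -> rare) and exports an iTOL annotation.

suppressPackageStartupMessages(library(oxascreen))

cat20 <- load_catalogue(default_catalogue())
cohort <- read_cohort("results/cohort/proteomes", "results/cohort/metadata.tsv")
hits_raw <- read.delim("results/screen/hits.tsv", colClasses = "character")
hits <- data.frame(class_id = hits_raw$class_id, strain_id = hits_raw$strain_id,
                   reference_id = hits_raw$qseqid, protein_id = hits_raw$sseqid,
                   stringsAsFactors = FALSE)

cn <- copy_number_matrix(hits, cohort, cat20)
dir.create("results/profile", recursive = TRUE, showWarnings = FALSE)
write_trait_matrix(cn, "results/profile/copy_number.tsv")
write_trait_matrix(trait_presence(cn), "results/profile/presence.tsv")
write_itol_binary(cn, "results/profile/itol_presence.txt")

profiles <- genus_percentages(cn, cohort)
write.table(profiles, "results/profile/genus_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cl <- presence_clusters(cn, k = 3)
write.table(cl, "results/profile/prevalence_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("prevalence clusters (1 = ubiquitous, 3 = rare):")
for (k in sort(unique(cl$cluster)))
  message("  cluster ", k, ": ",
          paste(cl$class_id[cl$cluster == k], collapse = ", "))
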