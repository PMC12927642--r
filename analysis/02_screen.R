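#!/usr/bin/env Rscript
# Stage 2: homology screen.
#
# Screens every proteome in results/cohort/ against the bundled reference
# enzyme database with the four-way hit filter (E <= 1e-3, bitscore >= 40,
# identity >= 30%, query coverage >= 60%) and writes the filtered hit
# table.

suppressPackageStartupMessages(library(oxascreen))

cat20 <- load_catalogue(default_catalogue())
refdb <- load_reference_db(default_reference_fasta(), cat20)
cohort <- read_cohort("results/cohort/proteomes", "results/cohort/metadata.tsv")

message("screening ", length(cohort), " proteomes against ",
        length(refdb$sequences), " reference sequences ...")
hits <- search_cohort(refdb, cohort)
dir.create("results/screen", recursive = TRUE, showWarnings = FALSE)
write_hits_tsv(hits, "results/screen/hits.tsv")
message(nrow(hits), " filtered hits across ",
        length(unique(hits$strain_id)), " strains and ",
        length(unique(hits$class_id)), " enzyme classes -> results/screen/hits.tsv")
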