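#!/usr/bin/env Rscript
# Stage 5: key-enzyme substitution analysis.
#
# Compares glyoxylate carboligase (Gcl) protein sequences between the
# cohort's oxalate-positive and oxalate-negative strains (as recorded in
# the simulation manifest), extracts group-discriminating substitutions
# and classifies them as conservative or non-conservative.

suppressPackageStartupMessages(library(oxascreen))

cohort <- read_cohort("results/cohort/proteomes", "results/cohort/metadata.tsv")
man <- jsonlite::read_json("results/cohort/manifest.json", simplifyVector = TRUE)
hits_raw <- read.delim("results/screen/hits.tsv", colClasses = "character")
hits <- data.frame(class_id = hits_raw$class_id, strain_id = hits_raw$strain_id,
                   reference_id = hits_raw$qseqid, protein_id = hits_raw$sseqid,
                   bitscore = as.numeric(hits_raw$bitscore),
                   stringsAsFactors = FALSE)

groups <- list(oxalate_positive = man$groups$oxalate_positive,
               oxalate_negative = man$groups$oxalate_negative)
seqs <- key_enzyme_sequences(hits, cohort, man$gcl_class)
cmp <- compare_groups(seqs, groups, man$reference_strain,
                      class_id = man$gcl_class)

dir.create("results/substitutions", recursive = TRUE, showWarnings = FALSE)
write_substitutions_tsv(cmp$records, "results/substitutions/substitutions.tsv")
jsonlite::write_json(cmp$summary, "results/substitutions/summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message("group-discriminating substitutions in ", man$gcl_class, ": ",
        cmp$summary$n_conservative, " conservative, ",
        cmp$summary$n_non_conservative, " non-conservative")
u <- unique(cmp$records[, c("reference_position", "from_residue",
                            "to_residue", "classification")])
for (i in seq_len(nrow(u)))
  message("  ", u$from_residue[i], u$reference_position[i], u$to_residue[i],
          " (", u$classification[i], ")")
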