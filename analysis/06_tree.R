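#!/usr/bin/env Rscript
# Stage 6: genome distance tree.
#
# Sketches every simulated genome (MinHash, k = 21, s = 1000 at this
# genome size), estimates pairwise Mash distances and builds the
# neighbor-joining context tree exported as Newick + PHYLIP.

suppressPackageStartupMessages(library(oxascreen))

meta <- read.delim("results/cohort/metadata.tsv", colClasses = "character")
sketches <- lapply(meta$strain_id, function(s)
  sketch_genome(file.path("results/cohort/genomes", paste0(s, ".fna")),
                k = 21, s = 1000, strain_id = s))

dm <- mash_distance_matrix(sketches)
dir.create("results/tree", recursive = TRUE, showWarnings = FALSE)
write_phylip(dm, "results/tree/distances.phylip")
tree <- neighbor_joining(dm)
write_newick(tree, "results/tree/tree.nwk")

message("tree over ", nrow(dm), " strains -> results/tree/tree.nwk")
message("mean off-diagonal mash distance: ",
        signif(mean(dm[upper.tri(dm)]), 4))
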