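#' Run the full oxalotrophy screen end to end
#'
#' Orchestrates screen -> profile -> classify -> substitutions -> tree over
#' a cohort on disk and writes every artifact into \code{output_dir}:
#' filtered hits (\code{hits.tsv}), copy-number and presence matrices,
#' genus occurrence profiles, prevalence clusters, toolkit calls, overlap
#' counts (TSV + JSON), an iTOL binary-trait annotation, and — when the
#' corresponding inputs are given — the substitution report and the
#' Mash/neighbor-joining Newick tree. A machine-readable run manifest
#' (config echo, package version, seed; no clock values) makes reruns
#' comparable: identical inputs and config yield byte-identical outputs.
#'
#' @param proteome_dir directory of \code{<strain_id>.faa} protein FASTAs.
#' @param metadata_tsv strain metadata TSV (strain_id, genus, phylum, host,
#'   site).
#' @param output_dir directory for results (created if needed).
#' @param catalogue_tsv,reference_fasta catalogue and reference database.
#' @param scheme a [scoring_scheme()].
#' @param filter a [hit_filter()].
#' @param focal_genera genera kept separate in overlap counts.
#' @param cluster_k prevalence cluster count.
#' @param substitution_spec optional list for the key-enzyme comparison:
#'   \code{class_id}, \code{reference_strain}, \code{groups} (list with
#'   \code{oxalate_positive} / \code{oxalate_negative} strain ids).
#' @param genome_dir optional directory of \code{<strain_id>.fna} genome
#'   FASTAs; triggers the distance-tree stage.
#' @param tree_k,tree_s MinHash k-mer size and sketch size.
#' @param seed recorded in the manifest (the screen itself is
#'   deterministic; the seed matters for upstream simulation).
#' @return (invisibly) list with the in-memory results: \code{hits},
#'   \code{copy_number}, \code{genus_profiles}, \code{clusters},
#'   \code{toolkit_calls}, \code{overlaps}, and optionally
#'   \code{substitutions} and \code{tree}.
#' @export
run_screen <- function(proteome_dir, metadata_tsv, output_dir,
                       catalogue_tsv = default_catalogue(),
                       reference_fasta = default_reference_fasta(),
                       scheme = scoring_scheme(), filter = hit_filter(),
                       focal_genera = "Pseudomonas", cluster_k = 3L,
                       substitution_spec = NULL, genome_dir = NULL,
                       tree_k = 21L, tree_s = 10000L, seed = NULL) {
  for (p in c(proteome_dir, metadata_tsv, catalogue_tsv, reference_fasta))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  catalogue <- load_catalogue(catalogue_tsv)
  refdb <- load_reference_db(reference_fasta, catalogue)
  cohort <- read_cohort(proteome_dir, metadata_tsv)

  hits <- search_cohort(refdb, cohort, scheme, filter)
  write_hits_tsv(hits, file.path(output_dir, "hits.tsv"))

  cn <- copy_number_matrix(hits, cohort, catalogue)
  write_trait_matrix(cn, file.path(output_dir, "copy_number.tsv"))
  write_trait_matrix(trait_presence(cn), file.path(output_dir, "presence.tsv"))
  write_itol_binary(cn, file.path(output_dir, "itol_presence.txt"))

  profiles <- genus_percentages(cn, cohort)
  write_tsv(profiles, file.path(output_dir, "genus_profiles.tsv"))
  clusters <- presence_clusters(cn, k = cluster_k)
  write_tsv(clusters, file.path(output_dir, "prevalence_clusters.tsv"))

  calls <- classify_cohort(cn)
  write_tsv(calls, file.path(output_dir, "toolkit_calls.tsv"))
  overlaps <- overlap_counts(calls, genus_grouping(cohort, focal_genera))
  write_tsv(overlaps, file.path(output_dir, "overlap_counts.tsv"))
  jsonlite::write_json(overlaps, file.path(output_dir, "overlap_counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- list(hits = hits, copy_number = cn, genus_profiles = profiles,
              clusters = clusters, toolkit_calls = calls, overlaps = overlaps)

  if (!is.null(substitution_spec)) {
    sp <- substitution_spec
    seqs <- key_enzyme_sequences(hits, cohort, sp$class_id)
    cmp <- compare_groups(seqs, sp$groups, sp$reference_strain,
                          scheme = scheme, class_id = sp$class_id)
    write_substitutions_tsv(cmp$records,
                            file.path(output_dir, "substitutions.tsv"))
    jsonlite::write_json(cmp$summary,
                         file.path(output_dir, "substitution_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$substitutions <- cmp
  }

  if (!is.null(genome_dir)) {
    strains <- vapply(cohort, `[[`, "", "strain_id")
    sketches <- lapply(strains, function(s) {
      f <- file.path(genome_dir, paste0(s, ".fna"))
      if (!file.exists(f)) stop("missing genome FASTA: ", f)
      sketch_genome(f, k = tree_k, s = tree_s, strain_id = s)
    })
    dm <- mash_distance_matrix(sketches)
    write_phylip(dm, file.path(output_dir, "distances.phylip"))
    write_tsv(cbind(data.frame(strain_id = rownames(dm)),
                    as.data.frame(dm, check.names = FALSE)),
              file.path(output_dir, "distances.tsv"))
    tree <- neighbor_joining(dm)
    write_newick(tree, file.path(output_dir, "tree.nwk"))
    res$tree <- tree
    res$distances <- dm
  }

  manifest <- list(
    package = "oxascreen",
    version = as.character(utils::packageVersion("oxascreen")),
    seed = seed,
    filter = unclass(filter),
    scheme = list(gap_open = scheme$gap_open, gap_extend = scheme$gap_extend,
                  lambda = scheme$lambda, K = scheme$K,
                  matrix = "BLOSUM62 (X neutral)"),
    focal_genera = focal_genera, cluster_k = cluster_k,
    tree = if (!is.null(genome_dir)) list(k = tree_k, s = tree_s),
    inputs = list(proteome_dir = proteome_dir, metadata_tsv = metadata_tsv,
                  catalogue_tsv = catalogue_tsv,
                  reference_fasta = reference_fasta,
                  genome_dir = genome_dir),
    n_strains = length(cohort), n_classes = nrow(catalogue))
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary_lines <- c(
    sprintf("oxascreen run: %d strains, %d enzyme classes, %d filtered hits",
            length(cohort), nrow(catalogue), nrow(hits)),
    sprintf("toolkit-complete strains: biomineralization %d, assimilation %d, both %d",
            sum(calls$biomineralization_complete),
            sum(calls$assimilation_complete),
            sum(calls$biomineralization_complete & calls$assimilation_complete)))
  writeLines(summary_lines, file.path(output_dir, "summary.txt"))

  invisible(res)
}

#' Extract each strain's best-matching protein for one enzyme class
#'
#' For the substitution stage: picks, per strain, the protein with the
#' highest-bitscore filtered hit to the class and returns its sequence.
#'
#' @param hits filtered hits.
#' @param cohort list of [proteome()] objects.
#' @param class_id catalogue class.
#' @return named character vector (strain id -> protein sequence) covering
#'   the strains that have at least one hit for the class.
#' @export
key_enzyme_sequences <- function(hits, cohort, class_id) {
  h <- hits[hits$class_id == class_id, , drop = FALSE]
  if (!nrow(h)) return(setNames(character(), character()))
  h <- h[order(-h$bitscore), ]
  best <- h[!duplicated(h$strain_id), ]
  setNames(
    vapply(seq_len(nrow(best)), function(i)
      cohort[[best$strain_id[i]]]$proteins[[best$protein_id[i]]], ""),
    best$strain_id)
}
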