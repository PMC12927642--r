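#' @name synthetic_cohort
#' @title Seeded synthetic cohorts with a ground-truth manifest
#'
#' @description
#' The generator builds a cohort that has the statistical structure the
#' screen assumes — per-strain proteomes with enzyme homologs planted at
#' controlled percent identity, query coverage and copy number among random
#' decoy proteins; strain metadata spanning several genera; a planted set
#' of group-discriminating substitutions in glyoxylate carboligase
#' separating oxalate-negative from oxalate-positive strains; and simulated
#' nucleotide genomes derived from one ancestor at per-strain mutation
#' rates. Every planting decision is recorded in a truth manifest so each
#' pipeline stage can be scored exactly. All output is a deterministic
#' function of the config and its mandatory seed.
NULL

# Swiss-Prot-wide amino-acid background frequencies
AA_FREQS <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
              E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
              M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
              Y = 2.92, V = 6.87) / 100

#' Random protein from background residue frequencies
#'
#' Decoy proteins are sampled from proteome-wide residue frequencies (not
#' shuffles of the references) to avoid accidental high-scoring matches.
#' Uses the current RNG stream.
#'
#' @param n length in residues.
#' @return amino-acid string.
#' @export
random_protein <- function(n) {
  paste(sample(names(AA_FREQS), n, replace = TRUE, prob = AA_FREQS),
        collapse = "")
}

#' Mutate a protein to a target percent identity
#'
#' Substitutes residues at uniformly chosen positions until the realised
#' identity is within 2 percentage points of the target (the tolerance
#' acknowledges the discreteness of short sequences). Each replacement is
#' drawn from the reference residue's BLOSUM62-positive partners with
#' probability 0.5, otherwise uniformly from the other residues, so
#' mutated homologs carry a realistic mix of conservative and
#' non-conservative changes. No indels are introduced.
#'
#' @param reference amino-acid string.
#' @param target_identity percent in (0, 100].
#' @param seed optional integer; when given the mutation is drawn from a
#'   private RNG stream and is reproducible in isolation.
#' @param scheme scoring scheme supplying the positive-partner sets.
#' @return mutated amino-acid string of the same length.
#' @export
mutate_protein <- function(reference, target_identity, seed = NULL,
                           scheme = scoring_scheme()) {
  if (target_identity <= 0 || target_identity > 100)
    stop("target_identity must be in (0, 100]")
  run <- function() {
    chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
    L <- length(chars)
    n_mut <- round(L * (1 - target_identity / 100))
    realized <- 100 * (L - n_mut) / L
    if (abs(realized - target_identity) > 2)
      stop("target identity ", target_identity,
           "% unattainable within +/-2 points on a ", L,
           "-residue sequence; use a longer reference")
    if (n_mut == 0L) return(reference)
    pos <- sample.int(L, n_mut)
    for (p in pos) {
      ref_res <- chars[p]
      partners <- AA20[scheme$matrix[ref_res, AA20] > 0 & AA20 != ref_res]
      chars[p] <- if (length(partners) && runif(1) < 0.5)
        sample(partners, 1L)
      else
        sample(setdiff(AA20, ref_res), 1L)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Synthetic cohort configuration
#'
#' Defaults describe the study conditions the test-bed emulates: 30 strains
#' over 5 genera with a Pseudomonas-heavy skew (mirroring real culture
#' collections from arid-soil isolations), homologs planted at 40-95%
#' identity and 70-100% query coverage, copy numbers 1-3 when present,
#' 50 decoys per strain, assimilation-pathway enzymes common and the
#' biomineralization toolkit rarer, three group-discriminating glyoxylate
#' carboligase substitutions (A>D and G>W non-conservative, I>V
#' conservative) carried by two oxalate-negative strains, and 50 kb genomes
#' mutated from one ancestor at rates 0 / 0.01 / 0.05 / 0.1 per site.
#'
#' @param seed mandatory integer seed; all generator output is a
#'   deterministic function of the config including this seed.
#' @param genera named integer vector: strains per genus (first genus hosts
#'   the substitution-plan subclade).
#' @param phylum_of named character: phylum per genus.
#' @param presence_prob named numeric over catalogue class ids:
#'   per-genus probability that a strain carries the class.
#' @param copy_probs probabilities of 1, 2 or 3 copies given presence.
#' @param identity_range,coverage_range planted homolog targets (percent).
#' @param decoys_per_strain,decoy_length_range decoy count and lengths.
#' @param substitution_plan data.frame with \code{class_id},
#'   \code{pos_frac}, \code{from}, \code{to}: substitutions planted in
#'   every oxalate-negative strain of the subclade.
#' @param n_negative number of oxalate-negative strains in the subclade.
#' @param genome_length,mutation_rates genome simulation parameters; rates
#'   are recycled across strains.
#' @param catalogue_tsv,reference_fasta catalogue and reference DB paths.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(seed,
                          genera = c(Pseudomonas = 10L, Bacillus = 8L,
                                     Streptomyces = 5L, Rhizobium = 4L,
                                     Flavobacterium = 3L),
                          phylum_of = c(Pseudomonas = "Pseudomonadota",
                                        Bacillus = "Bacillota",
                                        Streptomyces = "Actinomycetota",
                                        Rhizobium = "Pseudomonadota",
                                        Flavobacterium = "Bacteroidota"),
                          presence_prob = NULL,
                          copy_probs = c(`1` = 0.7, `2` = 0.2, `3` = 0.1),
                          identity_range = c(40, 95),
                          coverage_range = c(70, 100),
                          decoys_per_strain = 50L,
                          decoy_length_range = c(80L, 400L),
                          substitution_plan = data.frame(
                            class_id = "4.1.1.47",
                            pos_frac = c(0.25, 0.50, 0.75),
                            from = c("A", "I", "G"),
                            to = c("D", "V", "W"),
                            stringsAsFactors = FALSE),
                          n_negative = 2L,
                          genome_length = 50000L,
                          mutation_rates = c(0, 0.01, 0.05, 0.1),
                          catalogue_tsv = default_catalogue(),
                          reference_fasta = default_reference_fasta()) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot_scalar_num(seed, "seed")
  if (is.null(presence_prob)) {
    cat20 <- load_catalogue(catalogue_tsv)
    assim_core <- c("1.2.1.17", "2.8.3.2", "2.1.2.1", "1.1.1.29", "4.1.1.47",
                    "1.1.1.60", "2.7.1.31", "1.1.1.26")
    presence_prob <- setNames(rep(0.5, nrow(cat20)), cat20$class_id)
    presence_prob[intersect(assim_core, cat20$class_id)] <- 0.9
    presence_prob[c("4.1.1.8", "2.8.3.16", "OxlT")] <- 0.35
    presence_prob["2.6.1.45"] <- 0.4
    presence_prob[intersect(c("3.7.1.1", "1.2.3.5"), cat20$class_id)] <- 0.3
  }
  if (any(presence_prob < 0 | presence_prob > 1))
    stop("presence probabilities must be in [0, 1]")
  if (any(identity_range < 0 | identity_range > 100))
    stop("identity_range must lie within [0, 100]")
  structure(list(seed = as.integer(seed), genera = genera,
                 phylum_of = phylum_of, presence_prob = presence_prob,
                 copy_probs = copy_probs, identity_range = identity_range,
                 coverage_range = coverage_range,
                 decoys_per_strain = as.integer(decoys_per_strain),
                 decoy_length_range = as.integer(decoy_length_range),
                 substitution_plan = substitution_plan,
                 n_negative = as.integer(n_negative),
                 genome_length = as.integer(genome_length),
                 mutation_rates = mutation_rates,
                 catalogue_tsv = catalogue_tsv,
                 reference_fasta = reference_fasta),
            class = "cohort_config")
}

# best score-only bitscore of each candidate protein against any reference
best_ref_bitscore <- function(seqs, refdb, scheme) {
  best <- rep(0, length(seqs))
  for (rid in names(refdb$sequences)) {
    raw <- local_scores(refdb$sequences[[rid]], seqs, scheme)
    best <- pmax(best, bitscore(raw, scheme))
  }
  best
}

# pick, for each plan row, a position of residue `from` near pos_frac * L
plan_positions <- function(base_chars, plan) {
  L <- length(base_chars)
  used <- integer()
  pos <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    anchor <- max(1L, min(L, round(plan$pos_frac[i] * L)))
    cand <- setdiff(which(base_chars == plan$from[i]), used)
    if (!length(cand))
      stop("no residue '", plan$from[i], "' available for substitution planting")
    pos[i] <- cand[which.min(abs(cand - anchor))]
    used <- c(used, pos[i])
  }
  pos
}

#' Generate a synthetic cohort of proteomes
#'
#' Builds per-strain proteomes (planted homologs embedded among decoys),
#' strain metadata and the truth manifest. Decoys that could pass the hit
#' filter against any reference (bitscore at or above the filter floor) are
#' discarded and resampled so the manifest's zero cells are true zeros;
#' planted homologs are likewise resampled if they cross-match a reference
#' of a different class.
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory; when given, writes
#'   \code{proteomes/<strain>.faa}, \code{metadata.tsv} and
#'   \code{manifest.json}.
#' @param scheme scoring scheme used for the decoy/cross-match post-checks.
#' @param filter hit filter whose bitscore floor drives the post-checks.
#' @return list with \code{cohort} (list of [proteome()]), \code{metadata}
#'   (data.frame), \code{manifest} (truth: copy-number matrix, planting
#'   records, intended toolkit calls, phenotype groups, substitution
#'   records) and \code{config}.
#' @export
generate_cohort <- function(config, dir = NULL, scheme = scoring_scheme(),
                            filter = hit_filter()) {
  catalogue <- load_catalogue(config$catalogue_tsv)
  refdb <- load_reference_db(config$reference_fasta, catalogue)
  with_seed(config$seed, generate_cohort_impl(config, catalogue, refdb,
                                              dir, scheme, filter))
}

generate_cohort_impl <- function(config, catalogue, refdb, dir, scheme,
                                 filter) {
  genera <- rep(names(config$genera), config$genera)
  n <- length(genera)
  strain_ids <- sprintf("SYN%03d", seq_len(n))
  hosts <- sample(c("Avicennia marina", "Phoenix dactylifera",
                    "Citrullus colocynthis", "Zygophyllum sp."), n, TRUE)
  sites <- sample(c("Thuwal", "Wadi Rum", "Al Ula", "Jizan"), n, TRUE)
  metadata <- data.frame(strain_id = strain_ids, genus = genera,
                         phylum = unname(config$phylum_of[genera]),
                         host = hosts, site = sites, stringsAsFactors = FALSE)

  classes <- catalogue$class_id
  refs_by_class <- split(names(refdb$class_of), unname(refdb$class_of))
  copy_truth <- matrix(0L, n, length(classes),
                       dimnames = list(strain_ids, classes))

  # subclade carrying the substitution plan: all strains of the first genus
  subclade <- strain_ids[genera == names(config$genera)[1L]]
  plan <- config$substitution_plan
  gcl_class <- plan$class_id[1L]
  gcl_ref <- refdb$sequences[[refs_by_class[[gcl_class]][1L]]]
  base_gcl <- mutate_protein(gcl_ref, 92)
  base_chars <- strsplit(base_gcl, "", fixed = TRUE)[[1L]]
  sub_pos <- plan_positions(base_chars, plan)
  neg_chars <- base_chars
  neg_chars[sub_pos] <- plan$to
  neg_gcl <- paste(neg_chars, collapse = "")
  negatives <- utils::tail(subclade, config$n_negative)
  positives <- setdiff(subclade, negatives)
  substitution_truth <- data.frame(
    class_id = plan$class_id, reference_position = sub_pos,
    from_residue = plan$from, to_residue = plan$to,
    classification = classify_substitution(plan$from, plan$to, scheme),
    stringsAsFactors = FALSE)

  plantings <- list()
  cohort <- vector("list", n)
  for (si in seq_len(n)) {
    sid <- strain_ids[si]
    prots <- character(); pnames <- character()
    add_protein <- function(seq) {
      pnames <<- c(pnames, sprintf("%s_p%03d", sid, length(pnames) + 1L))
      prots <<- c(prots, seq)
      pnames[length(pnames)]
    }
    for (cl in classes) {
      forced_gcl <- cl == gcl_class && sid %in% subclade
      copies <- if (forced_gcl) 1L
      else if (runif(1) < config$presence_prob[[cl]])
        sample(as.integer(names(config$copy_probs)), 1L,
               prob = config$copy_probs)
      else 0L
      if (copies == 0L) next
      copy_truth[sid, cl] <- copies
      for (cp in seq_len(copies)) {
        if (forced_gcl) {
          seq <- if (sid %in% negatives) neg_gcl else base_gcl
          tgt_id <- 92; tgt_cov <- 100
        } else {
          rid <- sample(refs_by_class[[cl]], 1L)
          ref <- refdb$sequences[[rid]]
          tgt_id <- runif(1, config$identity_range[1], config$identity_range[2])
          tgt_cov <- runif(1, config$coverage_range[1], config$coverage_range[2])
          L <- nchar(ref)
          flen <- max(25L, round(tgt_cov / 100 * L))
          fstart <- sample.int(L - flen + 1L, 1L)
          frag <- substr(ref, fstart, fstart + flen - 1L)
          core <- mutate_protein(frag, tgt_id, scheme = scheme)
          # cross-match post-check against other classes' references
          for (try in 1:20) {
            other <- refdb$sequences[setdiff(names(refdb$sequences),
                                             refs_by_class[[cl]])]
            cross <- best_ref_bitscore(core, structure(
              list(sequences = other), class = "reference_db"), scheme)
            if (cross < filter$min_bitscore) break
            core <- mutate_protein(frag, tgt_id, scheme = scheme)
          }
          flank <- function() if ((fl <- sample(0:15, 1L)) > 0)
            random_protein(fl) else ""
          seq <- paste0(flank(), core, flank())
        }
        pid <- add_protein(seq)
        plantings[[length(plantings) + 1L]] <- data.frame(
          strain_id = sid, class_id = cl, protein_id = pid,
          target_identity = tgt_id, target_coverage = tgt_cov,
          stringsAsFactors = FALSE)
      }
    }
    # decoys, resampled until none can reach the bitscore floor
    lens <- sample(config$decoy_length_range[1]:config$decoy_length_range[2],
                   config$decoys_per_strain, replace = TRUE)
    decoys <- vapply(lens, random_protein, "")
    for (try in 1:20) {
      bad <- which(best_ref_bitscore(decoys, refdb, scheme) >=
                     filter$min_bitscore)
      if (!length(bad)) break
      decoys[bad] <- vapply(lens[bad], random_protein, "")
    }
    for (d in decoys) add_protein(d)
    cohort[[si]] <- proteome(sid, setNames(prots, pnames),
                             genus = metadata$genus[si],
                             phylum = metadata$phylum[si],
                             host = metadata$host[si],
                             site = metadata$site[si])
  }
  names(cohort) <- strain_ids
  class(copy_truth) <- c("trait_matrix", class(copy_truth))
  toolkit_truth <- classify_cohort(copy_truth)
  manifest <- list(
    copy_number = copy_truth,
    plantings = do.call(rbind, c(plantings, list(make.row.names = FALSE))),
    toolkit_calls = toolkit_truth,
    groups = list(oxalate_positive = positives, oxalate_negative = negatives),
    reference_strain = positives[1L],
    substitutions = substitution_truth,
    gcl_class = gcl_class)
  out <- list(cohort = cohort, metadata = metadata, manifest = manifest,
              config = config)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

write_cohort <- function(sim, dir) {
  pdir <- file.path(dir, "proteomes")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  for (p in sim$cohort) {
    aa <- Biostrings::AAStringSet(p$proteins)
    Biostrings::writeXStringSet(aa, file.path(pdir, paste0(p$strain_id, ".faa")),
                                width = 60L)
  }
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  man <- sim$manifest
  man$copy_number <- cbind(data.frame(strain_id = rownames(man$copy_number)),
                           as.data.frame(unclass(man$copy_number),
                                         check.names = FALSE))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate genomes from a shared ancestor
#'
#' One random ancestor sequence of \code{genome_length} is mutated
#' independently per strain: each site flips to a different base with the
#' strain's per-site mutation rate (rates recycled from
#' \code{config$mutation_rates}). The manifest records the rates and the
#' realised pairwise nucleotide divergences.
#'
#' @param config a [cohort_config()].
#' @param dir optional directory; writes \code{genomes/<strain>.fna}.
#' @return list with \code{genomes} (named character), \code{rates}
#'   (named numeric) and \code{divergence} (pairwise realised difference
#'   fractions).
#' @export
generate_genomes <- function(config, dir = NULL) {
  with_seed(derive_seed(config$seed, "genomes"), {
    genera <- rep(names(config$genera), config$genera)
    strain_ids <- sprintf("SYN%03d", seq_along(genera))
    L <- config$genome_length
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    rates <- setNames(rep_len(config$mutation_rates, length(strain_ids)),
                      strain_ids)
    genomes <- vapply(strain_ids, function(s) {
      g <- anc
      nm <- stats::rbinom(1L, L, rates[[s]])
      if (nm > 0) {
        pos <- sample.int(L, nm)
        g[pos] <- vapply(g[pos], function(b) sample(setdiff(bases, b), 1L), "")
      }
      paste(g, collapse = "")
    }, "")
    div <- matrix(0, length(strain_ids), length(strain_ids),
                  dimnames = list(strain_ids, strain_ids))
    raws <- lapply(genomes, charToRaw)
    if (length(strain_ids) > 1)
      for (i in 1:(length(strain_ids) - 1))
        for (j in (i + 1):length(strain_ids))
          div[i, j] <- div[j, i] <- sum(raws[[i]] != raws[[j]]) / L
    if (!is.null(dir)) {
      gdir <- file.path(dir, "genomes")
      dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
      for (s in strain_ids)
        Biostrings::writeXStringSet(
          Biostrings::DNAStringSet(setNames(genomes[s], s)),
          file.path(gdir, paste0(s, ".fna")), width = 70L)
    }
    list(genomes = genomes, rates = rates, divergence = div)
  })
}
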