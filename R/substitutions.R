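#' Extract amino-acid substitutions from a pairwise alignment
#'
#' One record per aligned column where both rows carry a residue and the
#' residues differ, with positions mapped to reference coordinates.
#' Columns where the reference row has a gap (insertions in the other
#' sequence) are not substitutions; they are skipped and tallied in the
#' \code{"n_insertions"} attribute, and deletions (gap in the other row)
#' in \code{"n_deletions"}.
#'
#' @param alignment an [alignment]; by convention the reference sequence is
#'   the query row (set \code{reference_is_query = FALSE} if it is the
#'   subject row).
#' @param reference_is_query which row is the reference.
#' @param strain_id strain carried on the records.
#' @param scheme scoring scheme used for [classify_substitution()].
#' @return data.frame with \code{strain_id}, \code{reference_position}
#'   (1-based on the full reference sequence), \code{from_residue},
#'   \code{to_residue} and \code{classification}.
#' @export
extract_substitutions <- function(alignment, reference_is_query = TRUE,
                                  strain_id = alignment$subject_id,
                                  scheme = scoring_scheme()) {
  if (reference_is_query) {
    ref <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1L]]
    oth <- strsplit(alignment$aligned_subject, "", fixed = TRUE)[[1L]]
    ref_start <- alignment$query_start
  } else {
    ref <- strsplit(alignment$aligned_subject, "", fixed = TRUE)[[1L]]
    oth <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1L]]
    ref_start <- alignment$subject_start
  }
  ref_pos <- ref_start - 1L + cumsum(ref != "-")
  is_sub <- ref != "-" & oth != "-" & ref != oth
  out <- data.frame(
    strain_id = rep(strain_id, sum(is_sub)),
    reference_position = ref_pos[is_sub],
    from_residue = ref[is_sub], to_residue = oth[is_sub],
    stringsAsFactors = FALSE)
  out$classification <- if (nrow(out))
    classify_substitution(out$from_residue, out$to_residue, scheme)
  else character()
  attr(out, "n_insertions") <- sum(ref == "-")
  attr(out, "n_deletions") <- sum(ref != "-" & oth == "-")
  out
}

#' Classify a substitution as conservative or non-conservative
#'
#' A replacement between biochemically similar residues is conservative;
#' the operational rule is a non-negative substitution-matrix score
#' (BLOSUM62 by default), which is deterministic and symmetric in the two
#' residues. Vectorised.
#'
#' @param from_residue,to_residue single residue letters (must differ).
#' @param scheme a [scoring_scheme()] supplying the matrix.
#' @return character vector, \code{"conservative"} or
#'   \code{"non_conservative"}.
#' @examples
#' classify_substitution("I", "V")  # conservative
#' classify_substitution("A", "D")  # non_conservative
#' @export
classify_substitution <- function(from_residue, to_residue,
                                  scheme = scoring_scheme()) {
  from_residue <- toupper(from_residue); to_residue <- toupper(to_residue)
  if (any(from_residue == to_residue))
    stop("from and to residues are identical: not a substitution")
  ok <- from_residue %in% AA20 & to_residue %in% AA20
  if (!all(ok))
    stop("invalid residue in substitution pair: ",
         paste(from_residue[!ok], to_residue[!ok], collapse = ", "))
  ifelse(scheme$matrix[cbind(from_residue, to_residue)] >= 0,
         "conservative", "non_conservative")
}

#' Group-discriminating substitutions in a key enzyme
#'
#' Star-aligns every strain's sequence of one enzyme class to a reference
#' strain's sequence (global alignment) and extracts the substitutions that
#' separate an oxalate-negative from an oxalate-positive strain group: a
#' reference position is discriminating iff \emph{every} negative-group
#' strain differs from the reference there and \emph{every} positive-group
#' strain matches the reference. The summary counts unique
#' (position, from, to) substitutions; the record list keeps one row per
#' negative strain and position.
#'
#' @param sequences named character vector, one protein sequence per strain
#'   (all strains of both groups must be present).
#' @param groups list with character vectors \code{oxalate_positive} and
#'   \code{oxalate_negative} of strain ids; disjoint, both non-empty.
#' @param reference_strain strain whose sequence anchors the coordinates;
#'   must belong to the positive group.
#' @param scheme a [scoring_scheme()].
#' @param class_id label carried in the output.
#' @return list with \code{records} (discriminating
#'   \code{SubstitutionRecord}s as a data.frame), \code{summary} (list:
#'   \code{n_conservative}, \code{n_non_conservative}, \code{per_pair_counts}
#'   over unique substitutions) and \code{all_records} (every substitution
#'   against the reference, not just discriminating ones).
#' @export
compare_groups <- function(sequences, groups, reference_strain,
                           scheme = scoring_scheme(),
                           class_id = "4.1.1.47") {
  pos <- groups$oxalate_positive; neg <- groups$oxalate_negative
  if (!length(pos) || !length(neg))
    stop("both phenotype groups must be non-empty")
  if (length(intersect(pos, neg)))
    stop("phenotype groups must be disjoint")
  if (!reference_strain %in% pos)
    stop("reference strain must belong to the oxalate_positive group")
  missing <- setdiff(c(pos, neg), names(sequences))
  if (length(missing))
    stop("no ", class_id, " sequence for strain(s): ",
         paste(missing, collapse = ", "))
  ref_seq <- sequences[[reference_strain]]
  others <- setdiff(c(pos, neg), reference_strain)
  subs <- lapply(others, function(s) {
    aln <- global_align(ref_seq, sequences[[s]], scheme,
                        query_id = reference_strain, subject_id = s)
    extract_substitutions(aln, reference_is_query = TRUE,
                          strain_id = s, scheme = scheme)
  })
  names(subs) <- others
  all_records <- do.call(rbind, c(subs, list(make.row.names = FALSE)))
  # positions where every negative differs and every positive matches ref
  neg_others <- intersect(others, neg)
  pos_others <- intersect(others, pos)
  pos_sub_positions <- unique(unlist(
    lapply(subs[pos_others], `[[`, "reference_position")))
  neg_positions <- lapply(subs[neg_others], `[[`, "reference_position")
  disc_pos <- Reduce(intersect, neg_positions)
  disc_pos <- setdiff(disc_pos, pos_sub_positions)
  records <- all_records[all_records$strain_id %in% neg_others &
                           all_records$reference_position %in% disc_pos, ,
                         drop = FALSE]
  rownames(records) <- NULL
  records$class_id <- rep(class_id, nrow(records))
  uniq <- unique(records[, c("reference_position", "from_residue",
                             "to_residue", "classification")])
  per_pair <- table(paste0(uniq$from_residue, ">", uniq$to_residue))
  list(records = records,
       summary = list(
         n_conservative = sum(uniq$classification == "conservative"),
         n_non_conservative = sum(uniq$classification == "non_conservative"),
         per_pair_counts = as.list(per_pair)),
       all_records = all_records)
}

#' Write substitution records as TSV
#'
#' @param records data.frame of substitution records.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_substitutions_tsv <- function(records, path) {
  write_tsv(records, path)
  invisible(path)
}

#' Import an externally computed alignment in aligned-FASTA form
#'
#' Reads a multiple alignment (e.g. from an external aligner) and returns
#' the gapped rows, allowing [compare_groups()]-style analysis to bypass
#' the internal pairwise aligner: positions are taken from the chosen
#' reference row's ungapped coordinates.
#'
#' @param fasta path to an aligned FASTA (all records equal gapped length).
#' @return named character vector of gapped rows.
#' @export
read_aligned_fasta <- function(fasta) {
  aa <- Biostrings::readAAStringSet(fasta)
  rows <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  if (length(unique(nchar(rows))) != 1L)
    stop("aligned FASTA rows differ in gapped length")
  rows
}
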