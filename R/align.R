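#' Pairwise alignment container
#'
#' Lightweight record of one pairwise alignment: raw score, 1-based
#' inclusive residue coordinates on both sequences, and the two gapped rows
#' (equal length, \code{-} for gaps, never a gap in both rows of a column).
#' An empty local alignment (no positive-scoring cell) has raw score 0,
#' zero-length rows and all coordinates 0.
#'
#' @param query_id,subject_id sequence identifiers.
#' @param raw_score raw alignment score under the scheme that produced it.
#' @param query_start,query_end,subject_start,subject_end 1-based inclusive
#'   coordinates of the aligned spans.
#' @param aligned_query,aligned_subject gapped strings of equal length.
#' @param type \code{"local"} or \code{"global"}.
#' @return an object of class \code{alignment}.
#' @export
alignment <- function(query_id, subject_id, raw_score,
                      query_start, query_end, subject_start, subject_end,
                      aligned_query, aligned_subject, type = "local") {
  if (nchar(aligned_query) != nchar(aligned_subject))
    stop("aligned rows must have equal gapped length")
  structure(list(query_id = query_id, subject_id = subject_id,
                 raw_score = raw_score,
                 query_start = query_start, query_end = query_end,
                 subject_start = subject_start, subject_end = subject_end,
                 aligned_query = aligned_query,
                 aligned_subject = aligned_subject, type = type),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<%s alignment> %s[%d-%d] vs %s[%d-%d], raw score %s\n",
              x$type, x$query_id, x$query_start, x$query_end,
              x$subject_id, x$subject_start, x$subject_end,
              format(x$raw_score)))
  cat(" ", x$aligned_query, "\n ", x$aligned_subject, "\n", sep = "")
  invisible(x)
}

pwa_to_alignment <- function(pwa, query_id, subject_id, type) {
  pat <- Biostrings::pattern(pwa)
  sub <- Biostrings::subject(pwa)
  if (type == "global") {
    # alignedPattern/alignedSubject keep terminal gaps, which pattern()
    # and subject() trim; a global alignment must charge them
    aq <- as.character(Biostrings::alignedPattern(pwa))
    as <- as.character(Biostrings::alignedSubject(pwa))
  } else {
    aq <- as.character(pat)
    as <- as.character(sub)
  }
  names(aq) <- names(as) <- NULL
  if (nchar(aq) == 0L) {
    return(alignment(query_id, subject_id, raw_score = 0,
                     0L, 0L, 0L, 0L, "", "", type = type))
  }
  alignment(query_id, subject_id,
            raw_score = Biostrings::score(pwa),
            query_start = BiocGenerics::start(pat),
            query_end = BiocGenerics::end(pat),
            subject_start = BiocGenerics::start(sub),
            subject_end = BiocGenerics::end(sub),
            aligned_query = aq, aligned_subject = as, type = type)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Maximal-scoring local alignment of two protein sequences under the
#' scheme's substitution matrix and affine gap penalties. If no cell scores
#' positively the result is the empty alignment with raw score 0. The
#' reported alignment is deterministic for fixed inputs (the engine's DP
#' traceback order breaks ties among co-optimal alignments).
#'
#' @param query,subject non-empty amino-acid strings (20 canonical residues
#'   plus X).
#' @param scheme a [scoring_scheme()].
#' @param query_id,subject_id identifiers stored on the result.
#' @return an [alignment] of type \code{"local"}; \code{raw_score >= 0}.
#' @examples
#' a <- smith_waterman("HEAGAWGHEE", "PAWHEAE")
#' a$raw_score
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           query_id = "query", subject_id = "subject") {
  validate_aa(query, paste0("query '", query_id, "'"))
  validate_aa(subject, paste0("subject '", subject_id, "'"))
  pwa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  pwa_to_alignment(pwa, query_id, subject_id, "local")
}

#' Optimal global alignment (Needleman-Wunsch, affine gaps)
#'
#' End-to-end alignment of two protein sequences; used to compare orthologs
#' of a key enzyme across strains before substitution extraction. The raw
#' score may be negative for dissimilar sequences.
#'
#' @inheritParams smith_waterman
#' @return an [alignment] of type \code{"global"} spanning both sequences.
#' @export
global_align <- function(query, subject, scheme = scoring_scheme(),
                         query_id = "query", subject_id = "subject") {
  validate_aa(query, paste0("query '", query_id, "'"))
  validate_aa(subject, paste0("subject '", subject_id, "'"))
  pwa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  pwa_to_alignment(pwa, query_id, subject_id, "global")
}

#' Rescore the gapped rows of an alignment
#'
#' Recomputes the raw score from the aligned strings: substitution scores
#' over residue-residue columns minus \code{gap_open + gap_extend * L} for
#' every gap run of length L. Used as an internal consistency check — the
#' result must equal \code{alignment$raw_score}.
#'
#' @param alignment an [alignment].
#' @param scheme the [scoring_scheme()] that produced it.
#' @return numeric raw score.
#' @export
rescore_alignment <- function(alignment, scheme = scoring_scheme()) {
  q <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1L]]
  s <- strsplit(alignment$aligned_subject, "", fixed = TRUE)[[1L]]
  if (length(q) == 0L) return(0)
  if (any(q == "-" & s == "-")) stop("column with gaps in both rows")
  resid <- q != "-" & s != "-"
  sub_score <- sum(scheme$matrix[cbind(q[resid], s[resid])])
  gap_cost <- 0
  for (row in list(q, s)) {
    r <- rle(row == "-")
    gl <- r$lengths[r$values]
    if (length(gl))
      gap_cost <- gap_cost + sum(scheme$gap_open + scheme$gap_extend * gl)
  }
  sub_score - gap_cost
}
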