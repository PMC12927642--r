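#' Alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul statistical parameters used to convert raw alignment
#' scores into bitscores and E-values. The default is BLOSUM62 with gap
#' open 11 / extend 1 and the published gapped-search constants
#' lambda = 0.267, K = 0.041 for that scheme. \code{X} is treated as an
#' annotation artifact and scores 0 against every residue.
#'
#' @param matrix symmetric integer substitution matrix with residue
#'   dimnames covering at least the 20 canonical amino acids plus \code{X}.
#' @param gap_open positive penalty charged once per gap run.
#' @param gap_extend positive penalty charged per gap position;
#'   must not exceed \code{gap_open}. A gap of length L costs
#'   \code{gap_open + gap_extend * L}.
#' @param lambda,K Karlin-Altschul parameters (nats per raw-score unit; K
#'   the search-space scale constant), both > 0.
#' @return an object of class \code{scoring_scheme}.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["I", "V"]   # 3: conservative pair
#' @export
scoring_scheme <- function(matrix = blosum62x(), gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  if (!is.matrix(matrix) || is.null(dimnames(matrix)))
    stop("substitution matrix must have residue dimnames")
  if (!all(AA21 %in% rownames(matrix)) || !all(AA21 %in% colnames(matrix)))
    stop("substitution matrix must cover the 20 amino acids plus X")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  stopifnot_scalar_num(gap_open, "gap_open"); stopifnot_scalar_num(gap_extend, "gap_extend")
  stopifnot_scalar_num(lambda, "lambda");     stopifnot_scalar_num(K, "K")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' BLOSUM62 with neutral X
#'
#' The BLOSUM62 matrix restricted to the canonical alphabet, with the
#' \code{X} row and column set to 0 so unknown residues neither reward nor
#' penalise an alignment.
#'
#' @return 21 x 21 integer matrix.
#' @export
blosum62x <- function() {
  m <- get_blosum62()[AA21, AA21]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}

# Biostrings' bundled copy of the NCBI BLOSUM62
get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Bitscore from a raw alignment score
#'
#' \code{S' = (lambda * S - ln K) / ln 2}; strictly increasing in the raw
#' score.
#'
#' @param raw_score non-negative raw score(s).
#' @param scheme a [scoring_scheme()].
#' @return bitscore(s) in bits.
#' @export
bitscore <- function(raw_score, scheme = scoring_scheme()) {
  if (any(raw_score < 0)) stop("raw_score must be >= 0")
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' E-value from a bitscore
#'
#' Expected number of chance hits of at least this score in an
#' \code{query_len x db_residues} search space:
#' \code{E = m * n * 2^(-S')}. The search space is the proteome being
#' screened, recomputed per strain.
#'
#' @param bits bitscore(s).
#' @param query_len query (reference enzyme) length in residues, >= 1.
#' @param db_residues total residues in the searched proteome, >= 1.
#' @return E-value(s), non-negative, decreasing in \code{bits}.
#' @export
evalue <- function(bits, query_len, db_residues) {
  if (any(query_len < 1) || any(db_residues < 1))
    stop("query_len and db_residues must be >= 1")
  query_len * db_residues * 2^(-bits)
}

#' Percent identity of an alignment
#'
#' 100 x identical columns / total gapped columns (the BLAST \code{pident}
#' convention: gap columns count in the denominator).
#'
#' @param alignment a pairwise [alignment] object.
#' @return identity percentage in \[0, 100\].
#' @export
percent_identity <- function(alignment) {
  q <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1L]]
  s <- strsplit(alignment$aligned_subject, "", fixed = TRUE)[[1L]]
  if (length(q) == 0L) stop("zero-length alignment has no percent identity")
  100 * sum(q == s & q != "-") / length(q)
}

#' Query coverage of an alignment
#'
#' 100 x aligned query span / query length, from the single best local
#' alignment (no HSP tiling).
#'
#' @param alignment a pairwise [alignment] object.
#' @param query_len full query length in residues, >= 1.
#' @return coverage percentage in \[0, 100\].
#' @export
query_coverage <- function(alignment, query_len) {
  if (query_len < 1) stop("query_len must be >= 1")
  if (nchar(alignment$aligned_query) == 0L ||
      alignment$query_end < alignment$query_start) return(0)
  100 * (alignment$query_end - alignment$query_start + 1) / query_len
}

#' Hit filter thresholds
#'
#' The four-way filter applied to every candidate hit. Defaults are the
#' screen's operating point: E-value at most 1e-3, bitscore at least 40,
#' percent identity at least 30, query coverage at least 60 — all bounds
#' inclusive.
#'
#' @param max_evalue,min_bitscore,min_identity,min_coverage thresholds.
#' @return an object of class \code{hit_filter}.
#' @export
hit_filter <- function(max_evalue = 1e-3, min_bitscore = 40,
                       min_identity = 30, min_coverage = 60) {
  for (v in c(max_evalue, min_bitscore, min_identity, min_coverage))
    stopifnot_scalar_num(v, "threshold")
  if (max_evalue <= 0 || min_bitscore <= 0 || min_identity <= 0 ||
      min_coverage <= 0) stop("thresholds must be positive")
  structure(list(max_evalue = max_evalue, min_bitscore = min_bitscore,
                 min_identity = min_identity, min_coverage = min_coverage),
            class = "hit_filter")
}

#' Does a hit pass the four-way filter?
#'
#' TRUE iff E-value <= max_evalue AND bitscore >= min_bitscore AND
#' percent identity >= min_identity AND query coverage >= min_coverage.
#' All comparisons are inclusive, so a hit exactly at a threshold passes.
#' Vectorised over hits.
#'
#' @param hit a hit row (list or data.frame) with fields \code{evalue},
#'   \code{bitscore}, \code{percent_identity}, \code{query_coverage}.
#' @param filter a [hit_filter()].
#' @return logical vector.
#' @export
passes_filter <- function(hit, filter = hit_filter()) {
  hit$evalue <= filter$max_evalue &
    hit$bitscore >= filter$min_bitscore &
    hit$percent_identity >= filter$min_identity &
    hit$query_coverage >= filter$min_coverage
}
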