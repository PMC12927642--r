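#' @useDynLib oxascreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
#' @importFrom stats setNames runif cor
#' @importFrom utils read.delim write.table head combn
NULL

# canonical protein alphabet; X tolerated as an annotation artifact
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
AA21 <- c(AA20, "X")

#' Validate an amino-acid sequence
#'
#' Accepts the 20 canonical residues plus \code{X}; any other character
#' (including ambiguity codes B/J/Z/U/O) is rejected with the position of the
#' first offending residue.
#'
#' @param seq single amino-acid string.
#' @param what label used in the error message (e.g. a sequence id).
#' @return the validated sequence, invisibly.
#' @keywords internal
validate_aa <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  if (nchar(seq) == 0L) stop(what, " is empty")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA21)
  if (length(bad))
    stop("invalid residue '", chars[bad[1L]], "' in ", what,
         " at position ", bad[1L])
  invisible(seq)
}

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_len(nchar(p))) else as.numeric(p)
  }, numeric(1))
  as.integer((seed * 2654435.0 + sum(parts * 97003.0)) %% 2147483629)
}

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single number")
}

write_tsv <- function(df, path, ...) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, ...)
}
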