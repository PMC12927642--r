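#' MinHash sketch of a genome
#'
#' Bottom-s MinHash over canonical nucleotide k-mers: each k-mer over
#' A/C/G/T is canonicalised as the lexicographic minimum of itself and its
#' reverse complement (on the 2-bit encoding), hashed with a fixed 64-bit
#' mixing function (splitmix64) and masked to 53 bits so hash values are
#' exact R doubles; the sketch keeps the s smallest distinct values.
#' k-mers containing any other character (e.g. N) are skipped. Sketching is
#' fully deterministic.
#'
#' @param fasta path to a nucleotide FASTA (one genome, any number of
#'   contigs); alternatively pass sequences directly via \code{sequences}.
#' @param k k-mer length (default 21), 1..31.
#' @param s sketch size (default 10000).
#' @param strain_id identifier stored on the sketch.
#' @param sequences optional character vector of sequences, used instead of
#'   \code{fasta}.
#' @return object of class \code{sketch}: \code{strain_id}, \code{k},
#'   \code{sketch_size}, sorted \code{hashes} (length <= s) and
#'   \code{genome_kmer_count} (distinct canonical k-mers). A genome shorter
#'   than k yields an empty sketch with a warning.
#' @export
sketch_genome <- function(fasta = NULL, k = 21L, s = 10000L,
                          strain_id = "genome", sequences = NULL) {
  if (is.null(sequences)) {
    if (is.null(fasta)) stop("provide a FASTA path or sequences")
    dna <- Biostrings::readDNAStringSet(fasta)
    sequences <- as.character(dna)
  }
  res <- .sketch_kmers(toupper(sequences), as.integer(k), as.integer(s))
  if (length(res$hashes) == 0L)
    warning("no valid k-mers for ", strain_id, " (genome shorter than k?)")
  structure(list(strain_id = strain_id, k = as.integer(k),
                 sketch_size = as.integer(s), hashes = res$hashes,
                 genome_kmer_count = res$distinct_kmers),
            class = "sketch")
}

#' Mash distance between two sketches
#'
#' The Jaccard index j is estimated from the bottom-s values of the merged
#' hash union (the sketch estimator, not the raw intersection over union of
#' the two full sets); the distance is
#' \code{d = -(1/k) * log(2j / (1 + j))}. Identical sketches give d = 0;
#' disjoint sketches (j = 0) are capped at the documented value 1.0.
#'
#' @param a,b two [sketch_genome()] results with equal \code{k} and
#'   \code{sketch_size}.
#' @return non-negative distance; decreasing in j.
#' @export
mash_distance <- function(a, b) {
  if (a$k != b$k) stop("sketches have different k (", a$k, " vs ", b$k, ")")
  if (a$sketch_size != b$sketch_size)
    stop("sketches have different sketch size")
  if (!length(a$hashes) || !length(b$hashes)) return(1.0)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  bottom <- merged[seq_len(min(a$sketch_size, length(merged)))]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- shared / length(bottom)
  if (j == 0) return(1.0)
  d <- -(1 / a$k) * log(2 * j / (1 + j))
  if (d <= 0) 0 else d
}

#' Pairwise Mash distance matrix
#'
#' @param sketches list of [sketch_genome()] results.
#' @return symmetric matrix with zero diagonal, labelled by strain ids.
#' @export
mash_distance_matrix <- function(sketches) {
  labels <- vapply(sketches, `[[`, "", "strain_id")
  n <- length(sketches)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1) for (i in 1:(n - 1)) for (jj in (i + 1):n) {
    d <- mash_distance(sketches[[i]], sketches[[jj]])
    m[i, jj] <- m[jj, i] <- d
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-criterion with Studier-Keppler distance
#' updates, as implemented in \pkg{ape}); negative branch lengths, which NJ
#' can produce on non-additive input, are clamped to zero. On an additive
#' matrix the leaf-to-leaf path lengths of the result reproduce the input
#' exactly.
#'
#' @param m symmetric non-negative distance matrix with zero diagonal and
#'   at least 3 labelled rows.
#' @return an unrooted \code{phylo} tree.
#' @export
neighbor_joining <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is asymmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("distances must be non-negative")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

quote_newick_label <- function(lab) {
  needs <- grepl("[][ \t():;,']", lab)
  lab[needs] <- paste0("'", gsub("'", "''", lab[needs]), "'")
  lab
}

#' Serialise a tree to Newick text
#'
#' Writes branch lengths, quotes labels containing spaces or Newick
#' metacharacters, and terminates with \code{";"}. Re-parsing round-trips
#' topology and branch lengths.
#'
#' @param tree a \code{phylo} object.
#' @param path optional file to write to.
#' @return the Newick string (invisibly if \code{path} is given).
#' @export
write_newick <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) return(quote_newick_label(tree$tip.label[node]))
    parts <- vapply(kids[[as.character(node)]], function(e) {
      paste0(rec(tree$edge[e, 2]),
             ":", format(tree$edge.length[e], digits = 12, scientific = FALSE))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(rec(ntip + 1L), ";")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param m labelled symmetric distance matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phylip <- function(m, path) {
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(formatC(rownames(m)[i], width = -10),
                       sprintf("%.6f", m[i, ])), collapse = " ")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
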