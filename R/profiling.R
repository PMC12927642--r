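#' Copy-number trait matrix from filtered hits
#'
#' Builds the strains x enzyme-classes copy-number matrix. A cell counts
#' \emph{distinct} proteins of the strain with at least one filter-passing
#' hit to any reference of the class — a protein matched by several
#' reference variants of one class is a single gene copy. A protein that
#' passes filters against references of different classes counts toward
#' each such class (raw hit semantics; no best-class assignment). Strains
#' with no hits get all-zero rows.
#'
#' @param hits filtered hits from [search_cohort()].
#' @param cohort list of [proteome()] objects (fixes row order and
#'   dimensions).
#' @param catalogue a [load_catalogue()] result (fixes column order).
#' @return integer matrix of class \code{trait_matrix} with strain rows and
#'   class columns.
#' @export
copy_number_matrix <- function(hits, cohort, catalogue) {
  strains <- unname(vapply(cohort, `[[`, "", "strain_id"))
  classes <- catalogue$class_id
  m <- matrix(0L, nrow = length(strains), ncol = length(classes),
              dimnames = list(strains, classes))
  if (nrow(hits)) {
    bad_s <- setdiff(unique(hits$strain_id), strains)
    if (length(bad_s)) stop("hit(s) reference unknown strain: ",
                            paste(bad_s, collapse = ", "))
    bad_c <- setdiff(unique(hits$class_id), classes)
    if (length(bad_c)) stop("hit(s) reference unknown class: ",
                            paste(bad_c, collapse = ", "))
    key <- unique(hits[, c("strain_id", "class_id", "protein_id")])
    tab <- table(key$strain_id, key$class_id)
    m[rownames(tab), colnames(tab)] <- m[rownames(tab), colnames(tab)] +
      matrix(as.integer(tab), nrow = nrow(tab))
  }
  class(m) <- c("trait_matrix", class(m))
  m
}

#' Presence/absence view of a trait matrix
#'
#' @param matrix a [copy_number_matrix()].
#' @return logical matrix, TRUE where copy number >= 1.
#' @export
trait_presence <- function(matrix) {
  unclass(matrix) >= 1L
}

#' Per-genus enzyme occurrence percentages
#'
#' For each genus, the percentage of its strains carrying each enzyme class
#' (presence = copy number >= 1). Strains without genus metadata are
#' grouped under \code{"Unassigned"} with a warning.
#'
#' @param matrix a [copy_number_matrix()].
#' @param cohort the cohort the matrix was built from.
#' @return data.frame with \code{genus}, \code{n_strains} and one column
#'   per enzyme class holding percentages in \[0, 100\].
#' @export
genus_percentages <- function(matrix, cohort) {
  strains <- unname(vapply(cohort, `[[`, "", "strain_id"))
  stopifnot(identical(unname(rownames(matrix)), strains))
  genus <- unname(vapply(cohort, `[[`, "", "genus"))
  if (anyNA(genus) || any(genus == "")) {
    warning("strain(s) without genus metadata grouped under 'Unassigned'")
    genus[is.na(genus) | genus == ""] <- "Unassigned"
  }
  pres <- trait_presence(matrix)
  by_genus <- split(seq_along(strains), genus)
  out <- do.call(rbind, lapply(names(by_genus), function(g) {
    idx <- by_genus[[g]]
    pct <- 100 * colSums(pres[idx, , drop = FALSE]) / length(idx)
    cbind(data.frame(genus = g, n_strains = length(idx),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(pct), check.names = FALSE))
  }))
  rownames(out) <- NULL
  out
}

# exact 1-D k-means by dynamic programming over sorted values
# (contiguity of optimal clusters in 1-D makes the DP optimal)
kmeans_1d <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  sse <- function(i, j) { # within-SSE of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n); B <- matrix(0L, k, n)
  for (j in 1:n) { D[1, j] <- sse(1, j); B[1, j] <- 1L }
  if (k > 1) for (q in 2:k) for (j in q:n) {
    for (i in q:j) {
      v <- D[q - 1, i - 1] + sse(i, j)
      if (v < D[q, j] - 1e-12) { D[q, j] <- v; B[q, j] <- i }
    }
  }
  grp <- integer(n); j <- n
  for (q in k:1) { i <- B[q, j]; grp[ord[i:j]] <- q; j <- i - 1 }
  grp
}

#' Cluster enzyme classes by prevalence
#'
#' Partitions the catalogue classes into \code{k} prevalence groups
#' (fraction of strains with presence) using exact 1-D k-means (dynamic
#' programming over sorted prevalences, optimal in 1-D and deterministic).
#' Groups are numbered 1..k from highest to lowest mean prevalence,
#' mirroring the ubiquitous-to-rare gradient seen in real screens. With
#' tied prevalences group membership follows catalogue column order.
#'
#' @param matrix a [copy_number_matrix()].
#' @param k number of groups (default 3), \code{1 <= k <=} number of classes.
#' @return data.frame with \code{class_id}, \code{prevalence} and
#'   \code{cluster}.
#' @export
presence_clusters <- function(matrix, k = 3L) {
  classes <- colnames(matrix)
  if (k < 1 || k > length(classes))
    stop("k must be between 1 and the number of classes (", length(classes), ")")
  prev <- colMeans(trait_presence(matrix))
  grp <- kmeans_1d(prev, k)
  means <- tapply(prev, grp, mean)
  relabel <- setNames(rank(-means, ties.method = "first"), names(means))
  data.frame(class_id = classes, prevalence = unname(prev),
             cluster = as.integer(relabel[as.character(grp)]),
             stringsAsFactors = FALSE)
}

#' Write a trait matrix as TSV
#'
#' Strains as rows (first column \code{strain_id}), classes as columns.
#'
#' @param matrix a [copy_number_matrix()] or its presence view.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trait_matrix <- function(matrix, path) {
  df <- data.frame(strain_id = rownames(matrix),
                   matrix * 1L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Export presence/absence traits as an iTOL binary dataset
#'
#' Writes a DATASET_BINARY annotation block that iTOL can drop onto a tree
#' whose leaves are the strain ids. Columns follow descending copy-number
#' sums so the most common enzymes sit closest to the leaf labels.
#'
#' @param matrix a [copy_number_matrix()].
#' @param path output annotation file path.
#' @param label dataset label shown in iTOL.
#' @return \code{path}, invisibly.
#' @export
write_itol_binary <- function(matrix, path, label = "oxalate enzymes") {
  ord <- order(-colSums(unclass(matrix)))
  m <- trait_presence(matrix)[, ord, drop = FALSE]
  n <- ncol(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "DATASET_BINARY",
    "SEPARATOR COMMA",
    paste0("DATASET_LABEL,", label),
    "COLOR,#2a6f97",
    paste0("FIELD_SHAPES,", paste(rep("2", n), collapse = ",")),
    paste0("FIELD_LABELS,", paste(colnames(m), collapse = ",")),
    "DATA"), con)
  writeLines(paste(rownames(m),
                   apply(m * 1L, 1L, paste, collapse = ","), sep = ","), con)
  invisible(path)
}
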