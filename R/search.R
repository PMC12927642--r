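#' Read one proteome from a protein FASTA
#'
#' @param fasta path to the strain's protein FASTA.
#' @param strain_id strain identifier.
#' @param genus,phylum,host,site optional metadata.
#' @return an object of class \code{proteome}: strain metadata plus a named
#'   character vector of protein sequences.
#' @export
read_proteome <- function(fasta, strain_id, genus = NA_character_,
                          phylum = NA_character_, host = NA_character_,
                          site = NA_character_) {
  aa <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate protein ids in ", fasta, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  proteome(strain_id, setNames(as.character(aa), ids),
           genus = genus, phylum = phylum, host = host, site = site)
}

#' @rdname read_proteome
#' @param proteins named character vector of amino-acid sequences.
#' @export
proteome <- function(strain_id, proteins, genus = NA_character_,
                     phylum = NA_character_, host = NA_character_,
                     site = NA_character_) {
  structure(list(strain_id = strain_id, genus = genus, phylum = phylum,
                 host = host, site = site, proteins = proteins),
            class = "proteome")
}

#' Read a cohort of proteomes
#'
#' @param proteome_dir directory of per-strain FASTA files named
#'   \code{<strain_id>.faa}.
#' @param metadata_tsv TSV with columns \code{strain_id}, \code{genus},
#'   \code{phylum}, \code{host}, \code{site}; one proteome is loaded per row.
#' @return list of \code{proteome} objects, named by strain id.
#' @export
read_cohort <- function(proteome_dir, metadata_tsv) {
  meta <- read.delim(metadata_tsv, sep = "\t", colClasses = "character")
  if (!"strain_id" %in% names(meta)) stop("metadata needs a strain_id column")
  if (anyDuplicated(meta$strain_id))
    stop("duplicate strain_id in metadata")
  get <- function(col, i) if (col %in% names(meta)) meta[[col]][i] else NA_character_
  out <- lapply(seq_len(nrow(meta)), function(i) {
    f <- file.path(proteome_dir, paste0(meta$strain_id[i], ".faa"))
    if (!file.exists(f)) stop("missing proteome FASTA: ", f)
    read_proteome(f, meta$strain_id[i], genus = get("genus", i),
                  phylum = get("phylum", i), host = get("host", i),
                  site = get("site", i))
  })
  setNames(out, meta$strain_id)
}

empty_hits <- function() {
  data.frame(class_id = character(), strain_id = character(),
             reference_id = character(), protein_id = character(),
             raw_score = numeric(), bitscore = numeric(), evalue = numeric(),
             percent_identity = numeric(), query_coverage = numeric(),
             align_length = integer(), query_start = integer(),
             query_end = integer(), subject_start = integer(),
             subject_end = integer(), stringsAsFactors = FALSE)
}

# raw local-alignment scores of many subject proteins against one query,
# via the vectorised engine (score-only pass)
local_scores <- function(query_seq, subject_seqs, scheme) {
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subject_seqs), Biostrings::AAString(query_seq),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
  pmax(s, 0)
}

#' Screen one proteome against the reference enzyme database
#'
#' Aligns every reference sequence against every protein of the strain
#' (single best local alignment per pair, no HSP tiling), computes
#' bitscore, E-value, percent identity and query coverage, and returns the
#' hits that pass the four-way filter. The E-value search space is the
#' screened proteome itself (query length x total proteome residues),
#' recomputed per strain. A fast score-only pass prunes pairs that cannot
#' reach the bitscore/E-value thresholds before full alignments are
#' computed; the pruning is exact because both statistics are monotone in
#' the raw score.
#'
#' @param refdb a [load_reference_db()] result.
#' @param proteome a [proteome()].
#' @param scheme a [scoring_scheme()].
#' @param filter a [hit_filter()].
#' @return data.frame of filter-passing hits, one row per
#'   (reference, protein) pair, sorted by class id, protein id and
#'   descending bitscore. Columns: \code{class_id}, \code{strain_id},
#'   \code{reference_id}, \code{protein_id}, \code{raw_score},
#'   \code{bitscore}, \code{evalue}, \code{percent_identity},
#'   \code{query_coverage}, \code{align_length}, \code{query_start},
#'   \code{query_end}, \code{subject_start}, \code{subject_end}.
#' @export
search_proteome <- function(refdb, proteome, scheme = scoring_scheme(),
                            filter = hit_filter()) {
  prots <- proteome$proteins
  if (length(prots) == 0L) {
    warning("empty proteome for strain ", proteome$strain_id)
    return(empty_hits())
  }
  db_res <- sum(nchar(prots))
  rows <- list()
  for (rid in names(refdb$sequences)) {
    qseq <- refdb$sequences[[rid]]
    m <- nchar(qseq)
    raw <- local_scores(qseq, prots, scheme)
    bits <- bitscore(raw, scheme)
    ev <- evalue(bits, m, db_res)
    cand <- which(raw > 0 & bits >= filter$min_bitscore &
                    ev <= filter$max_evalue)
    for (i in cand) {
      pid_name <- names(prots)[i]
      aln <- smith_waterman(qseq, prots[[i]], scheme,
                            query_id = rid, subject_id = pid_name)
      pid <- percent_identity(aln)
      qcov <- query_coverage(aln, m)
      if (pid < filter$min_identity || qcov < filter$min_coverage) next
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = unname(refdb$class_of[[rid]]),
        strain_id = proteome$strain_id,
        reference_id = rid, protein_id = pid_name,
        raw_score = aln$raw_score, bitscore = bits[i], evalue = ev[i],
        percent_identity = pid, query_coverage = qcov,
        align_length = nchar(aln$aligned_query),
        query_start = aln$query_start, query_end = aln$query_end,
        subject_start = aln$subject_start, subject_end = aln$subject_end,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits[order(hits$class_id, hits$protein_id, -hits$bitscore), , drop = FALSE]
}

#' Screen a whole cohort
#'
#' @param cohort list of [proteome()] objects.
#' @inheritParams search_proteome
#' @return combined hits data.frame across strains.
#' @export
search_cohort <- function(refdb, cohort, scheme = scoring_scheme(),
                          filter = hit_filter()) {
  do.call(rbind, c(lapply(cohort, search_proteome, refdb = refdb,
                          scheme = scheme, filter = filter),
                   list(make.row.names = FALSE)))
}

#' Write hits in BLAST tabular (outfmt 6-like) order
#'
#' Columns: qseqid, sseqid, pident, length, qstart, qend, sstart, send,
#' evalue, bitscore, then class_id and strain_id. E-values are formatted in
#' scientific notation with 2 significant digits.
#'
#' @param hits a [search_proteome()]/[search_cohort()] result.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$reference_id, sseqid = hits$protein_id,
    pident = round(hits$percent_identity, 3), length = hits$align_length,
    qstart = hits$query_start, qend = hits$query_end,
    sstart = hits$subject_start, send = hits$subject_end,
    evalue = sprintf("%.1e", hits$evalue),
    bitscore = round(hits$bitscore, 1),
    class_id = hits$class_id, strain_id = hits$strain_id,
    stringsAsFactors = FALSE)
  write_tsv(out, path)
  invisible(path)
}
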