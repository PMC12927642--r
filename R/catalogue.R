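#' @name catalogue
#' @title The oxalate-metabolism enzyme catalogue
#'
#' @description
#' The screen is driven by a catalogue of 20 classes — 19 enzymes identified
#' by EC number plus the oxalate:formate antiporter \code{OxlT} — covering
#' oxalate biosynthesis, degradation and assimilation. Catalogue contents
#' are data, not code: the bundled table (see [default_catalogue()]) can be
#' replaced by any user table with the same columns.
#'
#' Two pathway toolkits are singled out for oxalotrophy calls:
#' \itemize{
#'   \item biomineralization: oxalyl-CoA decarboxylase (Oxc, EC 4.1.1.8),
#'     formyl-CoA transferase (Frc, EC 2.8.3.16) and the transporter OxlT;
#'   \item assimilation: glyoxylate carboligase (Gcl, EC 4.1.1.47),
#'     hydroxypyruvate reductase (EC 1.1.1.29) and serine-glyoxylate
#'     transaminase (EC 2.6.1.45).
#' }
NULL

PATHWAY_ROLES <- c("biomineralization", "assimilation", "biosynthesis", "other")

#' Load an enzyme catalogue from a TSV table
#'
#' @param catalogue_table path to a UTF-8 tab-separated file with header
#'   columns \code{class_id}, \code{display_name}, \code{pathway_roles}
#'   (semicolon-separated tokens from \{biomineralization, assimilation,
#'   biosynthesis, other\}) and \code{reference_ids} (semicolon-separated
#'   sequence identifiers).
#' @return an object of class \code{catalogue}: a data.frame with list
#'   columns \code{pathway_roles} and \code{reference_ids}, row order as in
#'   the file.
#' @examples
#' cat20 <- load_catalogue(default_catalogue())
#' nrow(cat20)                    # 20 classes
#' sum(cat20$class_id == "OxlT")  # exactly one transporter
#' @export
load_catalogue <- function(catalogue_table) {
  if (!file.exists(catalogue_table))
    stop("catalogue table not found: ", catalogue_table)
  df <- read.delim(catalogue_table, header = TRUE, sep = "\t",
                   colClasses = "character", quote = "")
  need <- c("class_id", "display_name", "pathway_roles", "reference_ids")
  if (!all(need %in% names(df)))
    stop("catalogue table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("catalogue table is empty: no classes defined")
  dup <- df$class_id[duplicated(df$class_id)]
  if (length(dup))
    stop("duplicate class_id in catalogue: ", paste(unique(dup), collapse = ", "))
  roles <- strsplit(df$pathway_roles, ";", fixed = TRUE)
  refs <- strsplit(df$reference_ids, ";", fixed = TRUE)
  bad <- setdiff(unlist(roles), PATHWAY_ROLES)
  if (length(bad))
    stop("unknown pathway_role token(s): ", paste(bad, collapse = ", "))
  if (any(lengths(roles) == 0L))
    stop("every class needs at least one pathway role")
  if (sum(df$class_id == "OxlT") != 1L)
    stop("catalogue must contain exactly one 'OxlT' entry")
  out <- data.frame(class_id = df$class_id, display_name = df$display_name,
                    stringsAsFactors = FALSE)
  out$pathway_roles <- roles
  out$reference_ids <- refs
  class(out) <- c("catalogue", "data.frame")
  out
}

#' Write a catalogue back to TSV
#'
#' Inverse of [load_catalogue()]; a write/load round trip reproduces the
#' catalogue field by field.
#'
#' @param catalogue a \code{catalogue}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  df <- data.frame(
    class_id = catalogue$class_id,
    display_name = catalogue$display_name,
    pathway_roles = vapply(catalogue$pathway_roles, paste, "", collapse = ";"),
    reference_ids = vapply(catalogue$reference_ids, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Path to the bundled default catalogue / reference FASTA
#'
#' The bundled catalogue carries the 20 default classes. The bundled
#' reference FASTA is \emph{synthetic} (deterministically generated
#' sequences, one or two per class) and exists so the workflow and its
#' tests run without downloads; a production screen should point
#' [load_reference_db()] at a curated FASTA of reviewed bacterial enzyme
#' sequences instead.
#'
#' @return file path inside the installed package.
#' @export
default_catalogue <- function() {
  system.file("extdata", "catalogue.tsv", package = "oxascreen", mustWork = TRUE)
}

#' @rdname default_catalogue
#' @export
default_reference_fasta <- function() {
  system.file("extdata", "reference_synthetic.faa", package = "oxascreen",
              mustWork = TRUE)
}

#' Load a reference enzyme database
#'
#' Reads a protein multi-FASTA of reference enzyme sequences and attaches
#' each record to its catalogue class via the catalogue's
#' \code{reference_ids}. When several references exist for one class all
#' are kept, to capture sequence diversity.
#'
#' @param fasta path to a protein multi-FASTA; record ids (first
#'   whitespace-delimited header token) must appear in the catalogue.
#' @param catalogue a [load_catalogue()] result.
#' @return an object of class \code{reference_db}: list with
#'   \code{sequences} (named character), \code{class_of} (named character,
#'   owning class per sequence id) and \code{total_residues}.
#' @export
load_reference_db <- function(fasta, catalogue) {
  if (!file.exists(fasta)) stop("reference FASTA not found: ", fasta)
  aa <- Biostrings::readAAStringSet(fasta)
  if (length(aa) == 0L) stop("reference FASTA is empty: ", fasta)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in reference FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- setNames(as.character(aa), ids)
  for (i in seq_along(seqs)) validate_aa(seqs[[i]], paste0("reference '", ids[i], "'"))
  class_of <- setNames(rep(catalogue$class_id, lengths(catalogue$reference_ids)),
                       unlist(catalogue$reference_ids))
  orphan <- setdiff(ids, names(class_of))
  if (length(orphan))
    stop("reference FASTA ids not mapped to any catalogue class: ",
         paste(orphan, collapse = ", "))
  covered <- unique(class_of[ids])
  missing <- setdiff(catalogue$class_id, covered)
  if (length(missing))
    stop("catalogue class(es) with no reference sequence: ",
         paste(missing, collapse = ", "))
  structure(list(sequences = seqs,
                 class_of = class_of[ids],
                 total_residues = sum(nchar(seqs))),
            class = "reference_db")
}

#' The two oxalotrophy pathway toolkits
#'
#' Constant definitions of the biomineralization toolkit
#' \{EC 4.1.1.8, EC 2.8.3.16, OxlT\} and the assimilation toolkit
#' \{EC 4.1.1.47, EC 1.1.1.29, EC 2.6.1.45\}. The member sets are disjoint;
#' a strain is called complete for a toolkit when every member class is
#' present in its proteome.
#'
#' @return named list of two \code{toolkit} objects, each with fields
#'   \code{name} and \code{member_class_ids}.
#' @export
toolkit_definitions <- function() {
  list(
    biomineralization = structure(
      list(name = "biomineralization",
           member_class_ids = c("4.1.1.8", "2.8.3.16", "OxlT")),
      class = "toolkit"),
    assimilation = structure(
      list(name = "assimilation",
           member_class_ids = c("4.1.1.47", "1.1.1.29", "2.6.1.45")),
      class = "toolkit"))
}
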