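#' Toolkit completeness call for one strain
#'
#' A toolkit is complete iff every member class is present (copy number
#' >= 1); completeness is binary and does not depend on copy number beyond
#' presence.
#'
#' @param presence_row named logical (or 0/1) vector of class presence for
#'   one strain; must cover every toolkit member class.
#' @param toolkits list of toolkits, default [toolkit_definitions()].
#' @param strain_id identifier stored on the call.
#' @return list of class \code{toolkit_call} with fields \code{strain_id},
#'   \code{biomineralization_complete}, \code{assimilation_complete} and
#'   \code{missing_classes} (named list of absent member classes per
#'   toolkit).
#' @examples
#' row <- c("4.1.1.8" = TRUE, "2.8.3.16" = TRUE, OxlT = TRUE,
#'          "4.1.1.47" = TRUE, "1.1.1.29" = TRUE, "2.6.1.45" = FALSE)
#' classify_strain(row, strain_id = "JZ006")$biomineralization_complete
#' @export
classify_strain <- function(presence_row, toolkits = toolkit_definitions(),
                            strain_id = "strain") {
  out <- list(strain_id = strain_id)
  missing <- list()
  for (tk in toolkits) {
    absent <- setdiff(tk$member_class_ids, names(presence_row))
    if (length(absent))
      stop("presence row for ", strain_id, " lacks toolkit class(es): ",
           paste(absent, collapse = ", "))
    miss <- tk$member_class_ids[!as.logical(presence_row[tk$member_class_ids])]
    missing[[tk$name]] <- miss
    out[[paste0(tk$name, "_complete")]] <- length(miss) == 0L
  }
  out$missing_classes <- missing
  class(out) <- "toolkit_call"
  out
}

#' Toolkit calls for a whole cohort
#'
#' @param matrix a [copy_number_matrix()].
#' @param toolkits list of toolkits, default [toolkit_definitions()].
#' @return data.frame with one row per strain: \code{strain_id},
#'   \code{biomineralization_complete}, \code{assimilation_complete},
#'   \code{missing_biomineralization}, \code{missing_assimilation}
#'   (semicolon-separated class lists).
#' @export
classify_cohort <- function(matrix, toolkits = toolkit_definitions()) {
  pres <- trait_presence(matrix)
  calls <- lapply(unname(rownames(pres)), function(s)
    classify_strain(pres[s, ], toolkits, strain_id = s))
  data.frame(
    strain_id = vapply(calls, `[[`, "", "strain_id"),
    biomineralization_complete =
      vapply(calls, `[[`, TRUE, "biomineralization_complete"),
    assimilation_complete =
      vapply(calls, `[[`, TRUE, "assimilation_complete"),
    missing_biomineralization = vapply(calls, function(x)
      paste(x$missing_classes$biomineralization, collapse = ";"), ""),
    missing_assimilation = vapply(calls, function(x)
      paste(x$missing_classes$assimilation, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

#' Venn-style toolkit overlap counts per strain group
#'
#' Partitions each group of strains into both-toolkits / biomineralization-
#' only / assimilation-only / neither; the four counts sum to the group
#' size. Typical grouping: a focal genus (e.g. Pseudomonas) versus the rest
#' of the cohort — see [genus_grouping()].
#'
#' @param calls a [classify_cohort()] data.frame.
#' @param grouping named character vector mapping strain_id to a group
#'   label; every strain in \code{calls} must be mapped.
#' @return data.frame with \code{group_label}, \code{n_strains},
#'   \code{n_both}, \code{n_biomin_only}, \code{n_assim_only},
#'   \code{n_neither}.
#' @export
overlap_counts <- function(calls, grouping) {
  if (nrow(calls) == 0L)
    return(data.frame(group_label = character(), n_strains = integer(),
                      n_both = integer(), n_biomin_only = integer(),
                      n_assim_only = integer(), n_neither = integer()))
  unmapped <- setdiff(calls$strain_id, names(grouping))
  if (length(unmapped))
    stop("strain(s) missing from grouping: ", paste(unmapped, collapse = ", "))
  grp <- grouping[calls$strain_id]
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    sel <- calls[grp == g, , drop = FALSE]
    b <- sel$biomineralization_complete
    a <- sel$assimilation_complete
    data.frame(group_label = g, n_strains = nrow(sel),
               n_both = sum(b & a), n_biomin_only = sum(b & !a),
               n_assim_only = sum(!b & a), n_neither = sum(!b & !a),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Focal-genus grouping for overlap counts
#'
#' Maps strains of the focal genera (default Pseudomonas) to their genus
#' name and everything else to \code{"other genera"}.
#'
#' @param cohort list of [proteome()] objects.
#' @param focal_genera character vector of genus names to keep separate.
#' @return named character vector suitable for [overlap_counts()].
#' @export
genus_grouping <- function(cohort, focal_genera = "Pseudomonas") {
  strains <- vapply(cohort, `[[`, "", "strain_id")
  genus <- vapply(cohort, `[[`, "", "genus")
  setNames(ifelse(genus %in% focal_genera, genus, "other genera"), strains)
}
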