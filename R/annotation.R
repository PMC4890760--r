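#' Regulatory annotation: modifiers, activators, inhibitors
#'
#' Pathway sources annotate reactions with regulating protein entities:
#' modifiers (phosphorylated proteins that catalyze a downstream transition),
#' activators (positive regulators) and inhibitors (negative regulators).
#' A protein maps to one or more genes: a multiprotein complex is a gene set
#' joined by `AND`, an isoform set is joined by `OR`.
#'
#' @param modifiers,activators,inhibitors data frames with columns
#'   `reaction_id`, `protein_id`.
#' @param proteins data frame with columns `protein_id`, `genes`
#'   (space-separated gene ids) and `relation` (`"and"` for complexes,
#'   `"or"` for isoform sets).
#' @return a `regulatory_annotation` object.
#' @export
regulatory_annotation <- function(modifiers = NULL, activators = NULL,
                                  inhibitors = NULL, proteins = NULL) {
  empty_link <- tibble::tibble(reaction_id = character(),
                               protein_id = character())
  as_link <- function(x) {
    if (is.null(x) || nrow(tibble::as_tibble(x)) == 0) return(empty_link)
    x <- tibble::as_tibble(x)
    stopifnot(all(c("reaction_id", "protein_id") %in% names(x)))
    x[, c("reaction_id", "protein_id")]
  }
  if (is.null(proteins) || nrow(tibble::as_tibble(proteins)) == 0) {
    proteins <- tibble::tibble(protein_id = character(), genes = character(),
                               relation = character())
  } else {
    proteins <- tibble::as_tibble(proteins)
    stopifnot(all(c("protein_id", "genes") %in% names(proteins)))
    if (is.null(proteins[["relation"]])) proteins$relation <- "and"
    proteins$relation[is.na(proteins$relation)] <- "and"
    stopifnot(all(proteins$relation %in% c("and", "or")))
    proteins <- proteins[, c("protein_id", "genes", "relation")]
  }
  structure(
    list(modifiers = as_link(modifiers), activators = as_link(activators),
         inhibitors = as_link(inhibitors), proteins = proteins),
    class = "regulatory_annotation"
  )
}

#' @export
print.regulatory_annotation <- function(x, ...) {
  cat("<regulatory_annotation> ", nrow(x$modifiers), " modifier, ",
      nrow(x$activators), " activator, ", nrow(x$inhibitors),
      " inhibitor links; ", nrow(x$proteins), " protein->gene entries\n",
      sep = "")
  invisible(x)
}

# Boolean expression (string) for one protein entity: complexes joined by
# AND, isoform sets by OR. A protein with no map entry falls back to its own
# id as the gene.
#' @noRd
protein_gene_expr <- function(annotation, protein_id) {
  row <- annotation$proteins[annotation$proteins$protein_id == protein_id, ]
  if (nrow(row) == 0L) return(protein_id)
  genes <- strsplit(trimws(row$genes[1]), "\\s+")[[1]]
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) return(NA_character_)
  if (length(genes) == 1L) return(genes)
  op <- if (row$relation[1] == "or") " OR " else " AND "
  paste(genes, collapse = op)
}

#' @noRd
annotation_empty <- function(annotation) {
  nrow(annotation$modifiers) + nrow(annotation$activators) +
    nrow(annotation$inhibitors) == 0L
}
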