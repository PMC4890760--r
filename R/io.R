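#' Read a stoichiometric model
#'
#' Supported formats: `"json"` (this package's canonical round-trip format),
#' `"table"` (a directory of TSV sheets named `Reactions`, `Species`, `GPRs`,
#' `Modifiers`, `Inhibitors`, `Activators`, `Proteins`, mirroring the workbook
#' layout commonly used to deposit such models) and `"sbml"` (SBML Level 2/3
#' core: species, reactions with stoichiometry, `listOfModifiers`). When the
#' source carries regulatory annotation it is attached to the model and is
#' available via [model_annotation()].
#'
#' @param path file (json/sbml) or directory (table) to read.
#' @param format one of `"auto"`, `"json"`, `"table"`, `"sbml"`; `"auto"`
#'   guesses from the path (directory -> table, `.xml`/`.sbml` -> sbml,
#'   otherwise json).
#' @return a `stoich_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "table", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "table"
    else if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
    else "json"
  }
  if (!file.exists(path)) stop("no such file or directory: ", path,
                               call. = FALSE)
  switch(format,
    json = read_model_json(path),
    table = read_model_table(path),
    sbml = read_model_sbml(path)
  )
}

#' Write a stoichiometric model
#'
#' The emitted file re-reads to an equal model (same ids, stoichiometry,
#' bounds and GPR rules); see [models_equal()].
#'
#' @param model a `stoich_model`.
#' @param path destination file (json) or directory (table; created).
#' @param format `"json"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "table")) {
  format <- match.arg(format)
  validate_stoich_model(model)
  switch(format,
    json = write_model_json(model, path),
    table = write_model_table(model, path)
  )
  invisible(path)
}

## ---- JSON ----

#' @noRd
read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("malformed JSON model file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  for (f in c("species", "reactions")) {
    if (is.null(doc[[f]])) stop("JSON model lacks element '", f, "'",
                                call. = FALSE)
  }
  ann <- NULL
  if (!is.null(doc$annotation)) {
    a <- doc$annotation
    ann <- regulatory_annotation(a$modifiers, a$activators, a$inhibitors,
                                 a$proteins)
  }
  model <- stoich_model(tibble::as_tibble(doc$reactions),
                        species = tibble::as_tibble(doc$species),
                        metadata = as.list(doc$metadata))
  model$annotation <- ann
  model
}

#' @noRd
write_model_json <- function(model, path) {
  doc <- list(
    format = "fluxtalk-model",
    version = 1L,
    metadata = model$metadata,
    species = model$species,
    reactions = model$reactions[, c("id", "equation", "lower_bound",
                                    "upper_bound", "gpr")]
  )
  if (!is.null(model$annotation)) {
    doc$annotation <- unclass(model$annotation)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
}

## ---- table dialect ----

#' @noRd
table_sheet_path <- function(dir, sheet) file.path(dir, paste0(sheet, ".tsv"))

#' @noRd
read_sheet <- function(dir, sheet, required = FALSE) {
  p <- table_sheet_path(dir, sheet)
  if (!file.exists(p)) {
    if (required) stop("table model is missing sheet '", sheet, "' (", p, ")",
                       call. = FALSE)
    return(NULL)
  }
  tibble::as_tibble(utils::read.delim(p, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      na.strings = c("NA", "")))
}

#' @noRd
read_model_table <- function(dir) {
  rx <- read_sheet(dir, "Reactions", required = TRUE)
  if (!all(c("id", "equation") %in% names(rx))) {
    stop("Reactions sheet needs columns id, equation", call. = FALSE)
  }
  sp <- read_sheet(dir, "Species")
  gp <- read_sheet(dir, "GPRs")
  if (!is.null(gp) && nrow(gp)) {
    gp <- gp[!is.na(gp$gpr) & nzchar(gp$gpr), ]
    rx$gpr <- gp$gpr[match(rx$id, gp$reaction_id)]
  }
  ann <- regulatory_annotation(
    modifiers = read_sheet(dir, "Modifiers"),
    activators = read_sheet(dir, "Activators"),
    inhibitors = read_sheet(dir, "Inhibitors"),
    proteins = read_sheet(dir, "Proteins")
  )
  model <- stoich_model(rx, species = sp)
  if (!annotation_empty(ann) || nrow(ann$proteins)) model$annotation <- ann
  model
}

#' @noRd
write_model_table <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, sheet) {
    utils::write.table(df, table_sheet_path(dir, sheet), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  wr(model$reactions[, c("id", "equation", "lower_bound", "upper_bound")],
     "Reactions")
  wr(model$species, "Species")
  has_gpr <- !is.na(model$reactions$gpr) & nzchar(model$reactions$gpr)
  wr(tibble::tibble(reaction_id = model$reactions$id[has_gpr],
                    gpr = model$reactions$gpr[has_gpr]), "GPRs")
  if (!is.null(model$annotation)) {
    a <- model$annotation
    wr(a$modifiers, "Modifiers")
    wr(a$activators, "Activators")
    wr(a$inhibitors, "Inhibitors")
    wr(a$proteins, "Proteins")
  }
}

## ---- SBML import ----

#' @noRd
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  ns_free <- function(node, what) {
    xml2::xml_find_all(node, paste0(".//*[local-name()='", what, "']"))
  }
  sp_nodes <- ns_free(doc, "species")
  if (length(sp_nodes) == 0L) stop("SBML file has no species", call. = FALSE)
  species <- tibble::tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           xml2::xml_attr(sp_nodes, "id"))
  )
  rx_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) stop("SBML file has no reactions", call. = FALSE)
  refs <- function(node, listname) {
    sr <- xml2::xml_find_all(node, paste0(
      "./*[local-name()='", listname, "']/*[local-name()='speciesReference']"))
    if (length(sr) == 0L) return(NULL)
    st <- xml2::xml_attr(sr, "stoichiometry")
    st <- ifelse(is.na(st), 1, as.numeric(st))
    stats::setNames(st, xml2::xml_attr(sr, "species"))
  }
  eqs <- character(length(rx_nodes))
  mods <- list()
  for (i in seq_along(rx_nodes)) {
    nd <- rx_nodes[[i]]
    lhs <- refs(nd, "listOfReactants")
    rhs <- refs(nd, "listOfProducts")
    side <- function(v) {
      if (is.null(v)) "" else paste(
        ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
    }
    eqs[i] <- paste(side(lhs), "->", side(rhs))
    mn <- xml2::xml_find_all(nd, paste0(
      "./*[local-name()='listOfModifiers']/",
      "*[local-name()='modifierSpeciesReference']"))
    if (length(mn)) {
      mods[[length(mods) + 1L]] <- tibble::tibble(
        reaction_id = xml2::xml_attr(nd, "id"),
        protein_id = xml2::xml_attr(mn, "species"))
    }
  }
  rx <- tibble::tibble(id = xml2::xml_attr(rx_nodes, "id"), equation = eqs)
  if (anyDuplicated(rx$id)) {
    stop("duplicate reaction ids in SBML file", call. = FALSE)
  }
  ann <- if (length(mods)) {
    regulatory_annotation(modifiers = dplyr::bind_rows(mods))
  } else NULL
  stoich_model(rx, species = species,
               metadata = list(source = basename(path), format = "sbml"),
               annotation = ann)
}
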