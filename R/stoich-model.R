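#' Stoichiometric signaling/metabolic network models
#'
#' A `stoich_model` holds an irreversible stoichiometric network: a species
#' table, a reaction table with flux bounds and optional gene-protein-reaction
#' (GPR) rules, and the m-by-r stoichiometric matrix S whose column j is
#' reaction j's stoichiometry (reactants negative, products positive). Under
#' the constraint-based formalism the admissible flux vectors v satisfy the
#' steady-state condition S v = 0 with `lower_bound <= v <= upper_bound`
#' elementwise. All reactions are irreversible, so lower bounds are
#' non-negative; flux is in arbitrary units (AU).
#'
#' @param reactions a data frame with columns `id`, `equation` (e.g.
#'   `"A + mod1 -> B + mod1p"`; `"-> A"` for a production exchange, `"A ->"`
#'   for secretion), and optionally `lower_bound`, `upper_bound` (defaults 0
#'   and 1000 AU) and `gpr` (Boolean rule string, `NA` for none).
#' @param species optional data frame with columns `id` and optionally `name`,
#'   `role` (one of `"signaling-component"`, `"modifier-product"`,
#'   `"boundary"`). Species mentioned only in equations are created with
#'   defaults.
#' @param metadata named list of provenance strings.
#' @param annotation optional [regulatory_annotation()]; species referenced
#'   only by the annotation (e.g. modifiers in a raw pathway) are allowed to
#'   be absent from the stoichiometry.
#' @return an object of class `stoich_model`.
#' @examples
#' m <- stoich_model(tibble::tibble(
#'   id = c("R1", "EX_A"),
#'   equation = c("A -> B", "-> A")
#' ))
#' classify_reactions(m)
#' @export
stoich_model <- function(reactions, species = NULL, metadata = list(),
                         annotation = NULL) {
  reactions <- tibble::as_tibble(reactions)
  if (!all(c("id", "equation") %in% names(reactions))) {
    stop("`reactions` needs columns `id` and `equation`", call. = FALSE)
  }
  if (is.null(reactions[["lower_bound"]])) reactions$lower_bound <- 0
  if (is.null(reactions[["upper_bound"]])) reactions$upper_bound <- 1000
  if (is.null(reactions[["gpr"]])) reactions$gpr <- NA_character_
  stoich <- lapply(reactions$equation, parse_equation)
  sp_ids <- unique(unlist(lapply(stoich, names)))
  if (is.null(species)) {
    species <- tibble::tibble(id = sp_ids)
  } else {
    species <- tibble::as_tibble(species)
    extra <- setdiff(sp_ids, species$id)
    if (length(extra)) {
      species <- dplyr::bind_rows(species, tibble::tibble(id = extra))
    }
  }
  if (is.null(species[["name"]])) species$name <- species$id
  if (is.null(species[["role"]])) species$role <- "signaling-component"
  species$name[is.na(species$name)] <- species$id[is.na(species$name)]
  species$role[is.na(species$role)] <- "signaling-component"

  S <- matrix(0, nrow(species), nrow(reactions),
              dimnames = list(species$id, reactions$id))
  for (j in seq_along(stoich)) S[names(stoich[[j]]), j] <- stoich[[j]]

  new_stoich_model(
    species = species[, c("id", "name", "role")],
    reactions = reactions[, c("id", "equation", "lower_bound",
                              "upper_bound", "gpr")],
    S = S, metadata = metadata, annotation = annotation
  )
}

#' @noRd
new_stoich_model <- function(species, reactions, S, metadata = list(),
                             annotation = NULL) {
  reactions$kind <- unname(ifelse(colSums(S != 0) == 1L, "exchange",
                                  "internal"))
  if (is.null(reactions[["tightened"]])) reactions$tightened <- FALSE
  reactions$tightened[is.na(reactions$tightened)] <- FALSE
  x <- structure(
    list(species = species, reactions = reactions, S = S,
         metadata = metadata, annotation = annotation),
    class = "stoich_model"
  )
  validate_stoich_model(x)
}

#' Validate a stoichiometric model's invariants
#'
#' Checks id uniqueness, matrix shape, irreversibility (`lower_bound >= 0`),
#' bound ordering, that exchange reactions touch exactly one species and
#' internal reactions have at least one reactant and one product, and that
#' every species appears in at least one reaction.
#'
#' @param x a `stoich_model`.
#' @return `x`, invisibly usable, after passing all checks.
#' @export
validate_stoich_model <- function(x) {
  sp <- x$species; rx <- x$reactions; S <- x$S
  if (anyDuplicated(sp$id)) stop("duplicate species ids", call. = FALSE)
  if (anyDuplicated(rx$id)) stop("duplicate reaction ids", call. = FALSE)
  if (!identical(dim(S), c(nrow(sp), nrow(rx)))) {
    stop("S must be m x r with m = |species|, r = |reactions|", call. = FALSE)
  }
  if (!identical(rownames(S), sp$id) || !identical(colnames(S), rx$id)) {
    stop("S dimnames must match species and reaction ids", call. = FALSE)
  }
  if (any(rx$lower_bound < 0)) {
    stop("all reactions are irreversible: lower_bound must be >= 0",
         call. = FALSE)
  }
  if (any(rx$lower_bound > rx$upper_bound)) {
    stop("lower_bound must not exceed upper_bound", call. = FALSE)
  }
  touched <- colSums(S != 0)
  if (any(touched == 0L)) {
    stop("reaction with empty stoichiometry: ",
         paste(rx$id[touched == 0L], collapse = ", "), call. = FALSE)
  }
  internal <- rx$kind == "internal"
  bad <- internal & (colSums(S < 0) == 0L | colSums(S > 0) == 0L)
  if (any(bad)) {
    stop("internal reactions need >= 1 reactant and >= 1 product: ",
         paste(rx$id[bad], collapse = ", "), call. = FALSE)
  }
  orphan <- rowSums(S != 0) == 0L
  if (any(orphan)) {
    # species referenced only as modifiers/activators/inhibitors are legal in
    # raw pathways; they join the stoichiometry via insert_modifiers()
    ann <- x$annotation
    referenced <- if (!is.null(ann)) {
      unique(c(ann$modifiers$protein_id, ann$activators$protein_id,
               ann$inhibitors$protein_id))
    } else character(0)
    orphan <- orphan & !sp$id %in% referenced
  }
  if (any(orphan)) {
    stop("species in no reaction: ", paste(sp$id[orphan], collapse = ", "),
         call. = FALSE)
  }
  bad_role <- !sp$role %in% c("signaling-component", "modifier-product",
                              "boundary")
  if (any(bad_role)) stop("unknown species role", call. = FALSE)
  x
}

# Parse "2 A + B -> C"; "-> A" produces, "A ->" consumes. Coefficients must be
# nonzero; duplicated species on one side are summed.
#' @noRd
parse_equation <- function(eq) {
  if (!grepl("->", eq, fixed = TRUE)) {
    stop("equation lacks '->': ", eq, call. = FALSE)
  }
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  sides <- c(sides, rep("", 2 - length(sides)))[1:2]
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (txt == "") return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      bits <- strsplit(tm, "\\s+")[[1]]
      if (length(bits) == 2L && !is.na(suppressWarnings(as.numeric(bits[1])))) {
        coef <- as.numeric(bits[1]); id <- bits[2]
      } else if (length(bits) == 1L) {
        coef <- 1; id <- bits
      } else {
        stop("cannot parse term '", tm, "' in equation: ", eq, call. = FALSE)
      }
      if (coef == 0) stop("zero stoichiometric coefficient in: ", eq,
                          call. = FALSE)
      out[id] <- (if (id %in% names(out)) out[id] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  all_ids <- union(names(lhs), names(rhs))
  coefs <- vapply(all_ids, function(id) {
    sum(lhs[names(lhs) == id]) + sum(rhs[names(rhs) == id])
  }, numeric(1))
  coefs <- coefs[coefs != 0]
  if (length(coefs) == 0L) {
    stop("equation cancels to nothing: ", eq, call. = FALSE)
  }
  coefs
}

#' @noRd
format_equation <- function(coefs) {
  fmt <- function(v) {
    vapply(seq_along(v), function(i) {
      cf <- abs(unname(v[i]))
      if (isTRUE(all.equal(cf, 1))) names(v)[i]
      else paste(format(cf, trim = TRUE), names(v)[i])
    }, character(1))
  }
  lhs <- coefs[coefs < 0]; rhs <- coefs[coefs > 0]
  paste(paste(fmt(lhs), collapse = " + "), "->",
        paste(fmt(rhs), collapse = " + ")) |> trimws()
}

#' Number of species / reactions
#' @param x a `stoich_model`.
#' @export
n_species <- function(x) nrow(x$species)

#' @rdname n_species
#' @export
n_reactions <- function(x) nrow(x$reactions)

#' Partition reactions into internal and exchange
#'
#' A reaction is an exchange reaction if and only if it touches exactly one
#' species (a boundary uptake or secretion); everything else is internal.
#'
#' @param x a `stoich_model`.
#' @return a tibble with columns `id` and `kind`; the partition is exhaustive
#'   and disjoint.
#' @export
classify_reactions <- function(x) {
  stopifnot(inherits(x, "stoich_model"))
  x$reactions[, c("id", "kind")]
}

#' Genes referenced by a model's GPR rules
#' @param x a `stoich_model`.
#' @return character vector of unique gene ids, sorted.
#' @export
model_genes <- function(x) {
  rules <- x$reactions$gpr
  rules <- rules[!is.na(rules) & nzchar(rules)]
  sort(unique(unlist(lapply(rules, function(r) gpr_genes(r)$gene))))
}

#' Regulatory annotation attached to a model
#' @param x a `stoich_model` read from a source that carries
#'   modifier/activator/inhibitor lists.
#' @return a `regulatory_annotation` or `NULL`.
#' @export
model_annotation <- function(x) x$annotation

#' @export
print.stoich_model <- function(x, ...) {
  kinds <- table(factor(x$reactions$kind, c("internal", "exchange")))
  n_gpr <- sum(!is.na(x$reactions$gpr) & nzchar(x$reactions$gpr))
  cat("<stoich_model> ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions (", kinds[["internal"]], " internal, ",
      kinds[["exchange"]], " exchange), ", n_gpr, " GPRs\n", sep = "")
  invisible(x)
}

# Replace bounds for given reaction ids.
#' @noRd
set_bounds <- function(model, ids, lower = NULL, upper = NULL) {
  i <- match(ids, model$reactions$id)
  stopifnot(!anyNA(i))
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  model
}

# Append reactions (and any new species) to a model.
#' @noRd
add_reactions <- function(model, reactions, species_roles = NULL) {
  reactions <- tibble::as_tibble(reactions)
  if (is.null(reactions[["gpr"]])) reactions$gpr <- NA_character_
  stoich <- lapply(reactions$equation, parse_equation)
  new_sp <- setdiff(unique(unlist(lapply(stoich, names))), model$species$id)
  sp <- model$species
  if (length(new_sp)) {
    roles <- if (is.null(species_roles)) "signaling-component" else
      species_roles[new_sp]
    roles[is.na(roles)] <- "signaling-component"
    sp <- dplyr::bind_rows(sp, tibble::tibble(id = new_sp, name = new_sp,
                                              role = unname(roles)))
  }
  S <- matrix(0, nrow(sp), ncol(model$S) + nrow(reactions),
              dimnames = list(sp$id, c(colnames(model$S), reactions$id)))
  S[rownames(model$S), colnames(model$S)] <- model$S
  for (j in seq_along(stoich)) {
    S[names(stoich[[j]]), ncol(model$S) + j] <- stoich[[j]]
  }
  rx <- dplyr::bind_rows(
    model$reactions,
    reactions[, c("id", "equation", "lower_bound", "upper_bound", "gpr")]
  )
  new_stoich_model(sp, rx, S, model$metadata, model$annotation)
}

# Drop reactions by id; species left orphaned are dropped too.
#' @noRd
drop_reactions <- function(model, ids) {
  keep <- !model$reactions$id %in% ids
  S <- model$S[, keep, drop = FALSE]
  rx <- model$reactions[keep, ]
  live <- rowSums(S != 0) > 0
  new_stoich_model(model$species[live, ], rx, S[live, , drop = FALSE],
                   model$metadata, model$annotation)
}

#' Test two models for equality of contents
#' @param a,b `stoich_model` objects.
#' @return `TRUE` or a character description of the first difference.
#' @export
models_equal <- function(a, b) {
  if (!identical(a$species$id, b$species$id)) return("species ids differ")
  if (!identical(a$species$role, b$species$role)) return("species roles differ")
  if (!identical(a$reactions$id, b$reactions$id)) return("reaction ids differ")
  if (!isTRUE(all.equal(unname(a$S), unname(b$S), tolerance = 1e-12))) {
    return("stoichiometry differs")
  }
  if (!isTRUE(all.equal(a$reactions$lower_bound, b$reactions$lower_bound)) ||
      !isTRUE(all.equal(a$reactions$upper_bound, b$reactions$upper_bound))) {
    return("bounds differ")
  }
  ga <- ifelse(is.na(a$reactions$gpr), "", a$reactions$gpr)
  gb <- ifelse(is.na(b$reactions$gpr), "", b$reactions$gpr)
  norm <- function(g) vapply(g, function(s) {
    if (!nzchar(s)) "" else gpr_deparse(gpr_parse(s))
  }, character(1), USE.NAMES = FALSE)
  if (!identical(norm(ga), norm(gb))) return("GPRs differ")
  TRUE
}
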