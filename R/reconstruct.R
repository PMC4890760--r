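#' Convert a raw pathway into a bounded constraint-based model
#'
#' Applies the default flux capacity to every reaction of a raw pathway
#' (as read from SBML or a tabular source): bounds become `[0, default_ub]`
#' AU, zero below because all reactions are irreversible. The pathway must
#' not yet contain exchange reactions — boundary exchanges are added later by
#' [add_minimal_exchanges()]. Regulatory annotation carried by the source is
#' passed through untouched.
#'
#' @param pathway a `stoich_model` (typically from [read_model()]).
#' @param default_ub default upper bound, AU (default 1000).
#' @return the bounded `stoich_model` (annotation preserved).
#' @export
convert_pathway <- function(pathway, default_ub = 1000) {
  stopifnot(inherits(pathway, "stoich_model"))
  if (n_reactions(pathway) == 0L) {
    stop("pathway has no reactions", call. = FALSE)
  }
  if (any(pathway$reactions$kind == "exchange")) {
    stop("raw pathway should not contain exchange reactions; ",
         "boundary exchanges are added by add_minimal_exchanges()",
         call. = FALSE)
  }
  pathway$reactions$lower_bound <- 0
  pathway$reactions$upper_bound <- default_ub
  validate_stoich_model(pathway)
}

#' Rewrite modifiers as co-substrates with spent products
#'
#' A modifier (a phosphorylated protein catalyzing a transition) is not a
#' reactant in the raw pathway, so it is disconnected from its targets. Each
#' modified reaction `A -> B` with modifier `mod` is rewritten to
#' `A + mod -> B + mod_p`, where the spent form `mod_p` is a new species with
#' role `"modifier-product"`; a production exchange `-> mod` and a
#' consumption exchange `mod_p ->` are added (once per modifier, shared
#' across reactions). The rewrite conserves the modifier: the added column
#' entries are -1 for `mod` and +1 for `mod_p`.
#'
#' @param model a `stoich_model`.
#' @param annotation a `regulatory_annotation`; defaults to the model's own.
#' @param default_ub upper bound for the added exchanges, AU.
#' @param suffix suffix for spent-modifier species ids (default `"_p"`); a
#'   registry resolves collisions with pre-existing ids.
#' @return the rewritten `stoich_model`.
#' @export
insert_modifiers <- function(model, annotation = model_annotation(model),
                             default_ub = 1000, suffix = "_p") {
  stopifnot(inherits(model, "stoich_model"))
  if (is.null(annotation) || nrow(annotation$modifiers) == 0L) return(model)
  mods <- annotation$modifiers
  bad <- setdiff(mods$reaction_id, model$reactions$id)
  if (length(bad)) stop("modifier annotation references unknown reactions: ",
                        paste(bad, collapse = ", "), call. = FALSE)

  # registry: one spent-product id per modifier species
  spent_of <- character(0)
  fresh_id <- function(base) {
    id <- base; k <- 1L
    while (id %in% model$species$id || id %in% spent_of) {
      k <- k + 1L
      id <- paste0(base, k)
    }
    id
  }

  new_species <- character(0)
  for (m in unique(mods$protein_id)) {
    sp_id <- fresh_id(paste0(m, suffix))
    spent_of[m] <- sp_id
    if (!m %in% model$species$id) new_species <- c(new_species, m)
  }

  S <- model$S
  # grow S for new rows (modifier species not yet present, spent products)
  add_rows <- c(new_species, unname(spent_of))
  S2 <- rbind(S, matrix(0, length(add_rows), ncol(S),
                        dimnames = list(add_rows, colnames(S))))
  for (i in seq_len(nrow(mods))) {
    rid <- mods$reaction_id[i]; m <- mods$protein_id[i]
    if (S2[m, rid] < 0) {
      stop("modifier '", m, "' already a reactant of reaction '", rid,
           "': ambiguous stoichiometry", call. = FALSE)
    }
    S2[m, rid] <- S2[m, rid] - 1
    S2[spent_of[m], rid] <- S2[spent_of[m], rid] + 1
  }

  sp <- dplyr::bind_rows(
    model$species,
    tibble::tibble(id = new_species, name = new_species,
                   role = "signaling-component"),
    tibble::tibble(id = unname(spent_of), name = unname(spent_of),
                   role = "modifier-product")
  )
  rx <- model$reactions
  # refresh equations of rewritten reactions
  for (rid in unique(mods$reaction_id)) {
    j <- match(rid, rx$id)
    col <- S2[, rid]
    rx$equation[j] <- format_equation(col[col != 0])
  }
  # exchanges, once per modifier species
  ex <- dplyr::bind_rows(lapply(unique(mods$protein_id), function(m) {
    tibble::tibble(
      id = c(paste0("EX_", m, "_in"), paste0("EX_", spent_of[m], "_out")),
      equation = c(paste("->", m), paste(spent_of[m], "->")),
      lower_bound = 0, upper_bound = default_ub, gpr = NA_character_
    )
  }))
  dup <- intersect(ex$id, rx$id)
  if (length(dup)) stop("exchange ids already in model: ",
                        paste(dup, collapse = ", "), call. = FALSE)
  Sx <- matrix(0, nrow(S2), nrow(ex), dimnames = list(rownames(S2), ex$id))
  for (j in seq_len(nrow(ex))) {
    coefs <- parse_equation(ex$equation[j])
    Sx[names(coefs), j] <- coefs
  }
  out <- new_stoich_model(
    sp,
    dplyr::bind_rows(rx, ex),
    cbind(S2, Sx),
    model$metadata, annotation
  )
  out
}

#' Build gene-protein-reaction rules from regulatory annotation
#'
#' Each annotated reaction receives a Boolean GPR: modifier and activator
#' proteins are expanded to their gene expressions (complexes with `AND`,
#' isoform sets with `OR`) and joined by `AND`; inhibitor proteins are joined
#' by `OR` and wrapped in `NOT` (any expressed inhibitor suppresses the
#' reaction); a reaction with both gets `modifiers AND NOT (inhibitors)`.
#' Modifier production/consumption exchanges receive the modifier's gene
#' expression. Reactions without any annotation get no rule. A protein whose
#' map entry has an empty gene list triggers a warning and is skipped; a
#' protein absent from the map is taken to be encoded by a gene of the same
#' id.
#'
#' @param model a `stoich_model`.
#' @param annotation a `regulatory_annotation`; defaults to the model's own.
#' @return the model with `gpr` strings filled in.
#' @export
build_gprs <- function(model, annotation = model_annotation(model)) {
  stopifnot(inherits(model, "stoich_model"))
  if (is.null(annotation)) return(model)
  expr_of <- function(pid) {
    e <- protein_gene_expr(annotation, pid)
    if (is.na(e)) {
      warning("protein '", pid, "' has no gene mapping; skipped",
              call. = FALSE)
    }
    e
  }
  # parenthesize only where needed to preserve precedence (AND binds tighter
  # than OR)
  wrap <- function(e) if (grepl(" OR ", e, fixed = TRUE)) paste0("(", e, ")")
    else e

  rx <- model$reactions
  for (j in seq_len(nrow(rx))) {
    rid <- rx$id[j]
    pos <- c(annotation$modifiers$protein_id[
               annotation$modifiers$reaction_id == rid],
             annotation$activators$protein_id[
               annotation$activators$reaction_id == rid])
    neg <- annotation$inhibitors$protein_id[
             annotation$inhibitors$reaction_id == rid]
    pos_e <- Filter(Negate(is.na), lapply(unique(pos), expr_of))
    neg_e <- Filter(Negate(is.na), lapply(unique(neg), expr_of))
    if (length(pos_e) == 0L && length(neg_e) == 0L) next
    parts <- character(0)
    if (length(pos_e)) {
      parts <- paste(vapply(pos_e, wrap, character(1)), collapse = " AND ")
    }
    if (length(neg_e)) {
      inner <- paste(unlist(neg_e), collapse = " OR ")
      notp <- if (length(neg_e) > 1L || grepl(" ", inner, fixed = TRUE)) {
        paste0("NOT (", inner, ")")
      } else paste("NOT", inner)
      parts <- c(parts, notp)
    }
    rx$gpr[j] <- paste(parts, collapse = " AND ")
  }

  # modifier exchanges inherit the modifier's genes
  for (m in unique(annotation$modifiers$protein_id)) {
    e <- protein_gene_expr(annotation, m)
    if (is.na(e)) next
    hit <- rx$kind == "exchange" &
      vapply(rx$id, function(id) {
        sp <- rownames(model$S)[model$S[, id] != 0]
        length(sp) == 1L && (sp == m || startsWith(sp, paste0(m, "_p")))
      }, logical(1))
    rx$gpr[hit & is.na(rx$gpr)] <- e
  }
  model$reactions <- rx
  model
}

#' Find dead-end species
#'
#' A dead end is a species that is only produced or only consumed: every
#' nonzero entry of its row of S has the same sign. Dead ends block
#' steady-state flux through their reactions.
#'
#' @param model a `stoich_model`.
#' @return character vector of dead-end species ids (possibly empty).
#' @export
find_dead_ends <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  S <- model$S
  one_sided <- apply(S, 1L, function(row) {
    nz <- row[row != 0]
    length(nz) > 0L && (all(nz > 0) | all(nz < 0))
  })
  rownames(S)[one_sided]
}

#' Close dead ends with a minimal exchange set
#'
#' Makes an infeasible pathway model feasible while keeping the boundary as
#' small as possible. The procedure: (1) a candidate exchange reaction with
#' bounds `[0, 0]` is added for every species; (2) internal lower bounds are
#' forced to `forced_lower` (default 1 AU) so every internal reaction must
#' carry flux; (3) [relax_rxns()] selects the minimum-cardinality candidate
#' set to relax; (4) only the selected exchanges are kept — split by achieved
#' flux direction into an uptake (`-> X`, id `EX_<X>_in`) or secretion
#' (`X ->`, id `EX_<X>_out`) reaction with bounds `[0, default_ub]` — and all
#' other candidates are removed; (5) internal lower bounds are restored.
#' The result has no dead ends, every internal reaction can carry flux
#' simultaneously, and re-running the function changes nothing.
#'
#' @param model a `stoich_model`.
#' @param forced_lower internal lower bound during the solve, AU (default 1).
#' @param big_M big-M constant (default 1000).
#' @param default_ub bounds ceiling for retained exchanges, AU.
#' @return the model with the minimal exchange set added. The selected set
#'   and amounts are attached as attribute `"relaxation"`.
#' @export
add_minimal_exchanges <- function(model, forced_lower = 1, big_M = 1000,
                                  default_ub = 1000) {
  stopifnot(inherits(model, "stoich_model"))
  sp_ids <- model$species$id
  cand <- tibble::tibble(
    id = paste0(".cand_EX_", sp_ids),
    equation = paste("->", sp_ids),
    lower_bound = 0, upper_bound = 0, gpr = NA_character_
  )
  if (any(cand$id %in% model$reactions$id)) {
    stop("reaction ids clash with candidate exchange ids", call. = FALSE)
  }
  aug <- add_reactions(model, cand)
  res <- relax_rxns(aug, cand$id, forced_lower = forced_lower, big_M = big_M)

  keep <- res$relaxed
  new_ex <- NULL
  if (length(keep)) {
    sp_of <- sub("^\\.cand_EX_", "", keep)
    dirn <- sign(res$v[keep])
    if (any(dirn == 0)) {
      # relaxed but zero flux cannot occur in a minimal solution; guard anyway
      keep <- keep[dirn != 0]; sp_of <- sp_of[dirn != 0]
      dirn <- dirn[dirn != 0]
    }
    new_ex <- tibble::tibble(
      id = unname(ifelse(dirn > 0, paste0("EX_", sp_of, "_in"),
                         paste0("EX_", sp_of, "_out"))),
      equation = unname(ifelse(dirn > 0, paste("->", sp_of),
                               paste(sp_of, "->"))),
      lower_bound = 0, upper_bound = default_ub, gpr = NA_character_
    )
  }
  out <- drop_reactions(aug, cand$id)
  if (!is.null(new_ex) && nrow(new_ex)) {
    dup <- intersect(new_ex$id, out$reactions$id)
    if (length(dup)) stop("exchange ids already present: ",
                          paste(dup, collapse = ", "), call. = FALSE)
    out <- add_reactions(out, new_ex)
  }
  attr(out, "relaxation") <- res
  out
}
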