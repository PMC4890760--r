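#' Specification for a synthetic signaling network with known ground truth
#'
#' Describes a small mass-balanced irreversible network plus the regulatory
#' and expression structure planted into it, so every pipeline stage can be
#' tested against exact ground truth computed at generation time. Internal
#' reactions are built reactant-to-product acyclic, which guarantees dead
#' ends exist before boundary exchanges are added.
#'
#' @param n_species number of species (ground-truth oracles require <= 20;
#'   the enumeration oracle is skipped above that).
#' @param topology `"chain"`, `"branch"`, `"diamond"` or `"random-dag"`.
#' @param n_modifiers,n_inhibitors how many reactions receive a modifier /
#'   inhibitor annotation.
#' @param planted_up_E,planted_up_M gene sets to plant as differentially
#'   expressed (character; must be genes the generated annotation creates,
#'   or they are drawn automatically when `NULL`).
#' @param n_planted_up_E,n_planted_up_M when the explicit sets are `NULL`,
#'   how many annotation genes to draw for each side.
#' @param effect planted absolute fold-change magnitude (must exceed
#'   `cutoff`).
#' @param cutoff fold-change cutoff the downstream classification will use.
#' @param seed integer seed; identical specs generate identical outputs.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_species = 6,
                           topology = c("chain", "branch", "diamond",
                                        "random-dag"),
                           n_modifiers = 0, n_inhibitors = 0,
                           planted_up_E = NULL, planted_up_M = NULL,
                           n_planted_up_E = 0, n_planted_up_M = 0,
                           effect = 3, cutoff = 2, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_species >= 2, effect > 0, cutoff > 0,
            n_modifiers >= 0, n_inhibitors >= 0)
  if (effect < cutoff) {
    stop("planted effect (", effect, ") must be at least the cutoff (",
         cutoff, ") or planted calls are unrecoverable", call. = FALSE)
  }
  if (topology == "diamond" && n_species < 4) {
    stop("diamond topology needs >= 4 species", call. = FALSE)
  }
  if (topology == "branch" && n_species < 3) {
    stop("branch topology needs >= 3 species", call. = FALSE)
  }
  structure(
    list(n_species = n_species, topology = topology,
         n_modifiers = n_modifiers, n_inhibitors = n_inhibitors,
         planted_up_E = planted_up_E, planted_up_M = planted_up_M,
         n_planted_up_E = n_planted_up_E, n_planted_up_M = n_planted_up_M,
         effect = effect, cutoff = cutoff, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic pathway with regulatory annotation and ground truth
#'
#' Builds the network described by the spec: one-to-one internal reactions
#' along the chosen acyclic topology, modifier annotations (each modifier
#' protein maps to one or two genes, complexes joined by `AND`), and
#' inhibitor annotations (one or two isoform genes, `OR`). Ground truth is
#' computed at generation time with independent oracles: the dead-end set
#' by a direct row-sign scan of S, and the minimal exchange cardinality by
#' exhaustive subset enumeration over per-species candidate exchanges with
#' a convex feasibility check per subset (networks with more than 20
#' species skip the enumeration and carry `NA`).
#'
#' @param spec a [synthetic_spec()].
#' @return a list: `pathway` (raw `stoich_model` carrying the annotation),
#'   `annotation`, and `truth` (list with `dead_ends`,
#'   `min_exchange_cardinality`, `inhibitor_reactions`).
#' @export
make_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_species
    sp <- sprintf("S%02d", seq_len(n))
    edges <- switch(spec$topology,
      chain = cbind(seq_len(n - 1), 2:n),
      branch = {
        hub <- 2L
        rbind(c(1L, hub),
              cbind(hub, seq.int(hub + 1L, n)))
      },
      diamond = {
        # split at S1, merge at S4, extra species chained after the merge
        base <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L))
        if (n > 4) base <- rbind(base, cbind(seq.int(4L, n - 1L),
                                             seq.int(5L, n)))
        base
      },
      "random-dag" = {
        # spanning path plus random forward edges keeps it connected, acyclic
        e <- cbind(seq_len(n - 1), 2:n)
        extra <- which(upper.tri(matrix(0, n, n)) &
                         stats::runif(n * n) < 1.5 / n, arr.ind = TRUE)
        extra <- extra[extra[, 2] - extra[, 1] > 1, , drop = FALSE]
        unique(rbind(e, extra))
      }
    )
    rx <- tibble::tibble(
      id = sprintf("R%02d", seq_len(nrow(edges))),
      equation = paste(sp[edges[, 1]], "->", sp[edges[, 2]])
    )
    model <- stoich_model(rx, species = tibble::tibble(id = sp),
                          metadata = list(source = "synthetic",
                                          topology = spec$topology,
                                          seed = spec$seed))

    pick <- function(k) sample(rx$id, min(k, nrow(rx)))
    mod_rx <- pick(spec$n_modifiers)
    inh_rx <- pick(spec$n_inhibitors)
    gene_counter <- 0L
    next_genes <- function(k) {
      out <- sprintf("g%03d", gene_counter + seq_len(k))
      gene_counter <<- gene_counter + k
      out
    }
    proteins <- list(); modifiers <- list(); inhibitors <- list()
    for (i in seq_along(mod_rx)) {
      pid <- sprintf("Pmod%02d", i)
      k <- sample(1:2, 1)
      proteins[[length(proteins) + 1L]] <- tibble::tibble(
        protein_id = pid, genes = paste(next_genes(k), collapse = " "),
        relation = "and")
      modifiers[[length(modifiers) + 1L]] <- tibble::tibble(
        reaction_id = mod_rx[i], protein_id = pid)
    }
    for (i in seq_along(inh_rx)) {
      pid <- sprintf("Pinh%02d", i)
      k <- sample(1:2, 1)
      proteins[[length(proteins) + 1L]] <- tibble::tibble(
        protein_id = pid, genes = paste(next_genes(k), collapse = " "),
        relation = "or")
      inhibitors[[length(inhibitors) + 1L]] <- tibble::tibble(
        reaction_id = inh_rx[i], protein_id = pid)
    }
    ann <- regulatory_annotation(
      modifiers = if (length(modifiers)) dplyr::bind_rows(modifiers),
      inhibitors = if (length(inhibitors)) dplyr::bind_rows(inhibitors),
      proteins = if (length(proteins)) dplyr::bind_rows(proteins)
    )
    model$annotation <- ann

    truth <- list(
      dead_ends = oracle_dead_ends(model$S),
      min_exchange_cardinality = if (n <= 20)
        oracle_min_exchanges(model, forced_lower = 1, big_M = 1000)
        else NA_integer_,
      inhibitor_reactions = sort(unique(inh_rx))
    )
    list(pathway = model, annotation = ann, truth = truth)
  })
}

# Independent dead-end oracle: plain row-sign scan.
#' @noRd
oracle_dead_ends <- function(S) {
  hits <- character(0)
  for (i in seq_len(nrow(S))) {
    nz <- S[i, S[i, ] != 0]
    if (length(nz) && (min(nz) > 0 || max(nz) < 0)) {
      hits <- c(hits, rownames(S)[i])
    }
  }
  hits
}

# Exhaustive minimal-exchange oracle: for increasing cardinality k, test
# every k-subset of per-species two-sided candidate exchanges for convex
# feasibility with internal lower bounds forced to `forced_lower`.
#' @noRd
oracle_min_exchanges <- function(model, forced_lower = 1, big_M = 1000,
                                 max_evals = 2e5) {
  S <- model$S
  m <- nrow(S)
  l <- model$reactions$lower_bound
  u <- model$reactions$upper_bound
  internal <- model$reactions$kind == "internal"
  l[internal] <- forced_lower
  feas_with <- function(sp_idx) {
    # candidate exchanges appear as extra +/-1 columns with wide bounds
    Sx <- cbind(S, diag(m)[, sp_idx, drop = FALSE])
    flux_feasible(Sx, c(l, rep(-big_M, length(sp_idx))),
                  c(u, rep(big_M, length(sp_idx))))
  }
  evals <- 0L
  for (k in 0:m) {
    for (set in combn_sets(seq_len(m), k)) {
      evals <- evals + 1L
      if (evals > max_evals) {
        stop("minimal-exchange oracle exceeded its evaluation budget",
             call. = FALSE)
      }
      if (feas_with(set)) return(k)
    }
  }
  NA_integer_
}

#' Generate an expression table with planted differential calls
#'
#' Planted `up_E` genes receive a fold change at or below `-effect` with a
#' significant p-value; `up_M` genes the mirror image; background genes
#' fall below the cutoff. The returned truth table is exactly what
#' [classify_regulation()] must recover at the spec's cutoff.
#'
#' @param spec a [synthetic_spec()].
#' @param model the annotated model from [make_network()] (after GPRs have
#'   been built, its genes define the gene universe), or a character vector
#'   of gene ids.
#' @return list: `table` (gene_id, fold_change, p_value) and `truth`
#'   (gene_id, state).
#' @export
make_expression <- function(spec, model) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- if (is.character(model)) model else model_genes(model)
  if (length(genes) == 0L) stop("model carries no genes", call. = FALSE)
  withr::with_seed(spec$seed + 1L, {
    up_E <- spec$planted_up_E
    up_M <- spec$planted_up_M
    if (is.null(up_E) && spec$n_planted_up_E > 0) {
      up_E <- sample(genes, min(spec$n_planted_up_E, length(genes)))
    }
    pool <- setdiff(genes, up_E)
    if (is.null(up_M) && spec$n_planted_up_M > 0) {
      up_M <- sample(pool, min(spec$n_planted_up_M, length(pool)))
    }
    bad <- setdiff(c(up_E, up_M), genes)
    if (length(bad)) stop("planted genes absent from the model: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    fold <- stats::runif(length(genes), -0.9, 0.9) * spec$cutoff
    pval <- stats::runif(length(genes), 0, 1)
    i_E <- genes %in% up_E
    i_M <- genes %in% up_M
    fold[i_E] <- -(spec$effect + stats::runif(sum(i_E), 0, 0.5))
    fold[i_M] <- spec$effect + stats::runif(sum(i_M), 0, 0.5)
    pval[i_E | i_M] <- stats::runif(sum(i_E | i_M), 1e-4, 0.01)
    state <- rep("unchanged", length(genes))
    state[i_E] <- "up_E"; state[i_M] <- "up_M"
    list(
      table = tibble::tibble(gene_id = genes, fold_change = fold,
                             p_value = pval),
      truth = tibble::tibble(gene_id = genes, state = state)
    )
  })
}

#' Generate a random regulation sign table with known true directions
#'
#' Random +1/-1 signs per gene for a declared regulating pathway, together
#' with the directions [predict_metabolic_expression()] must return under a
#' declared pathway flux fold change.
#'
#' @param genes nonempty character vector of gene ids.
#' @param pathway_fold the declared aggregate fold (mesenchymal over
#'   epithelial) the truth is computed under.
#' @param seed integer seed.
#' @param pathway pathway label (default `"AKT"`).
#' @return list: `table` (gene_id, pathway, sign, reference) and `truth`
#'   (gene_id, predicted).
#' @export
make_sign_table <- function(genes, pathway_fold = 0.5, seed = 1,
                            pathway = "AKT") {
  stopifnot(length(genes) > 0, pathway_fold > 0)
  withr::with_seed(as.integer(seed) + 2L, {
    sgn <- sample(c(-1, 1), length(genes), replace = TRUE)
    truth <- if (pathway_fold < 1) {
      ifelse(sgn == 1, "down_in_M", "down_in_E")
    } else if (pathway_fold > 1) {
      ifelse(sgn == 1, "down_in_E", "down_in_M")
    } else rep(NA_character_, length(genes))
    list(
      table = tibble::tibble(gene_id = genes, pathway = pathway, sign = sgn,
                             reference = "synthetic"),
      truth = tibble::tibble(gene_id = genes, predicted = truth)
    )
  })
}
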