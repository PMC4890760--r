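#' Minimal bound relaxations steering one context's flux toward another's
#'
#' A MOMA-like mixed-integer quadratic program: find a flux vector `v` in the
#' mesenchymal model's flux space — allowing a minimal set of reactions to
#' escape their bounds — that is as close as possible (Euclidean norm) to a
#' reference flux vector, typically the epithelial mean flux from sampling.
#' The objective is
#'
#' \deqn{\min \; \alpha \, \lVert v - v_E \rVert + (1 - \alpha)
#'   \sum_{j \in R_r} y_j}
#'
#' subject to the same steady-state, bound and big-M relaxation constraints
#' as [relax_rxns()], with bounds taken from the mesenchymal model. Solved
#' exactly by branch-and-bound over the relaxation indicators with a convex
#' QP (quadprog) per node; `method = "enumerate"` instead enumerates all
#' candidate subsets (the independent cross-check used in the tests, capped
#' at 20 candidates). Ties are resolved by (cardinality, total relaxation
#' amount, lexicographic reaction ids), making the output deterministic.
#'
#' @param model_M the mesenchymal-context `stoich_model` (its bounds define
#'   the feasible set).
#' @param v_E reference flux vector: a numeric vector indexed like
#'   `model_M`'s reactions (names are checked when present), or the tibble
#'   from [mean_flux()].
#' @param alpha weight in `[0, 1]` on the distance term. `alpha = 0` reduces
#'   to the pure relaxation-count objective; values near 1 buy flux
#'   proximity at any relaxation cost. Default 0.5 (always reported in the
#'   result).
#' @param candidates reaction ids allowed to relax; default all reactions.
#' @param big_M big-M constant (default 1000).
#' @param method `"bnb"` (exact branch-and-bound, default) or `"enumerate"`.
#' @param norm_scale `"raw"` (Euclidean norm, default) or `"relative"`
#'   (norm divided by `||v_E||`, making the two objective terms
#'   commensurate).
#' @return a `reversal_target`: `relaxed` ids, `p`/`n` amounts, achieved
#'   flux `v`, `distance` (Euclidean, raw scale), `objective` and its two
#'   terms, `alpha`, and the gene set of the relaxed reactions via GPRs.
#' @export
minimize_distance <- function(model_M, v_E, alpha = 0.5, candidates = NULL,
                              big_M = 1000, method = c("bnb", "enumerate"),
                              norm_scale = c("raw", "relative")) {
  method <- match.arg(method)
  norm_scale <- match.arg(norm_scale)
  stopifnot(inherits(model_M, "stoich_model"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  rx <- model_M$reactions
  if (is.data.frame(v_E)) {
    v_E <- stats::setNames(v_E$mean_flux, v_E$reaction_id)
  }
  if (!is.null(names(v_E))) {
    miss <- setdiff(rx$id, names(v_E))
    if (length(miss)) stop("v_E lacks entries for reactions: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    v_E <- v_E[rx$id]
  } else if (length(v_E) != nrow(rx)) {
    stop("v_E must be indexed like the model's reactions", call. = FALSE)
  }
  if (is.null(candidates)) candidates <- rx$id
  cand_idx <- match(candidates, rx$id)
  if (anyNA(cand_idx)) stop("unknown candidate reactions", call. = FALSE)

  S <- model_M$S
  l <- rx$lower_bound
  u <- rx$upper_bound
  scale <- if (norm_scale == "relative") sqrt(sum(v_E^2)) else 1
  if (scale == 0) scale <- 1

  dist_of <- function(set_idx) {
    b <- relaxed_bounds(l, u, set_idx, big_M)
    sol <- qp_nearest_flux(S, b$l, b$u, target = as.numeric(v_E))
    if (!sol$feasible) return(NULL)
    list(v = sol$v, dist = sqrt(max(sol$dist2, 0)))
  }
  obj_of <- function(set_idx, d) alpha * d / scale + (1 - alpha) *
    length(set_idx)

  base <- dist_of(integer(0))
  if (is.null(base) && is.null(dist_of(cand_idx))) {
    stop("model infeasible even with all candidates relaxed", call. = FALSE)
  }

  tol <- 1e-7
  best <- NULL  # list(set, v, dist, obj)
  consider <- function(set_idx) {
    sol <- dist_of(set_idx)
    if (is.null(sol)) return(invisible())
    cand <- list(set = sort(set_idx), v = sol$v, dist = sol$dist,
                 obj = obj_of(set_idx, sol$dist))
    if (is.null(best) || cand$obj < best$obj - tol) { best <<- cand;
      return(invisible()) }
    if (abs(cand$obj - best$obj) <= tol) {
      # tie-break: fewer relaxations, then smaller relaxation total, then ids
      key <- function(z) {
        amt <- relax_amounts_for(z$v, l, u, z$set)
        list(k = length(z$set), t = amt$total,
             ids = paste(rx$id[z$set], collapse = "|"))
      }
      a <- key(cand); b <- key(best)
      if (a$k < b$k || (a$k == b$k && (a$t < b$t - 1e-9 ||
          (abs(a$t - b$t) <= 1e-9 && a$ids < b$ids)))) best <<- cand
    }
    invisible()
  }

  if (method == "enumerate") {
    if (length(cand_idx) > 20L) {
      stop("enumeration capped at 20 candidates; use method = \"bnb\"",
           call. = FALSE)
    }
    for (k in 0:length(cand_idx)) {
      for (set in combn_sets(cand_idx, k)) consider(set)
    }
  } else {
    # branch and bound; node bound relaxes all free candidates for the
    # distance term and counts only committed relaxations
    all_sol <- dist_of(cand_idx)
    ordv <- if (!is.null(all_sol)) {
      viol <- pmax(all_sol$v[cand_idx] - u[cand_idx],
                   l[cand_idx] - all_sol$v[cand_idx], 0)
      cand_idx[order(-viol, rx$id[cand_idx])]
    } else cand_idx
    consider(integer(0))
    if (is.null(best)) consider(cand_idx)
    recurse <- function(included, free) {
      lower <- {
        sol <- dist_of(c(included, free))
        if (is.null(sol)) return(invisible())
        alpha * sol$dist / scale + (1 - alpha) * length(included)
      }
      if (!is.null(best) && lower > best$obj + tol) return(invisible())
      consider(included)
      if (length(free) == 0L) return(invisible())
      j <- free[1L]
      recurse(c(included, j), free[-1L])
      recurse(included, free[-1L])
    }
    recurse(integer(0), ordv)
  }

  amt <- relax_amounts_for(best$v, l, u, best$set)
  genes <- if (length(best$set)) {
    genes_for_reactions(model_M, rx$id[best$set])
  } else {
    tibble::tibble(gene = character(), inhibitor = logical())
  }
  structure(
    list(
      relaxed = rx$id[best$set], p = amt$p, n = amt$n,
      v = best$v, distance = best$dist,
      objective = best$obj,
      distance_term = alpha * best$dist / scale,
      cardinality_term = (1 - alpha) * length(best$set),
      alpha = alpha, big_M = big_M, norm_scale = norm_scale,
      genes = genes, model = model_M, v_E = v_E
    ),
    class = "reversal_target"
  )
}

# p/n amounts implied by an achieved flux for a fixed relaxed set.
#' @noRd
relax_amounts_for <- function(v, l, u, set_idx) {
  ids <- names(v)[set_idx]
  p <- pmax(v[set_idx] - u[set_idx], 0)
  n <- pmax(l[set_idx] - v[set_idx], 0)
  names(p) <- ids; names(n) <- ids
  list(p = p, n = n, total = sum(p) + sum(n))
}

#' @noRd
combn_sets <- function(x, k) {
  if (k == 0L) return(list(integer(0)))
  if (k > length(x)) return(list())
  utils::combn(x, k, simplify = FALSE)
}

#' @export
print.reversal_target <- function(x, ...) {
  cat("<reversal_target> alpha = ", x$alpha, "; ", length(x$relaxed),
      " relaxed reactions; distance ||v - v_E|| = ",
      format(x$distance, digits = 6), "\n", sep = "")
  if (length(x$relaxed)) {
    cat("  relaxed:", paste(x$relaxed, collapse = ", "), "\n")
    cat("  genes:", nrow(x$genes), "\n")
  }
  invisible(x)
}

#' Tidy a reversal target
#' @param x a `reversal_target`.
#' @param ... unused.
#' @return tibble with one row per relaxed reaction: `reaction_id`, `p`,
#'   `n`, `flux`, `target_flux`.
#' @export
tidy.reversal_target <- function(x, ...) {
  tibble::tibble(
    reaction_id = x$relaxed,
    p = unname(x$p[x$relaxed]),
    n = unname(x$n[x$relaxed]),
    flux = unname(x$v[x$relaxed]),
    target_flux = unname(x$v_E[x$relaxed])
  )
}

#' @rdname tidy.reversal_target
#' @export
glance.reversal_target <- function(x, ...) {
  tibble::tibble(
    n_relaxed = length(x$relaxed),
    distance = x$distance,
    objective = x$objective,
    distance_term = x$distance_term,
    cardinality_term = x$cardinality_term,
    alpha = x$alpha,
    n_genes = nrow(x$genes)
  )
}

#' Genes associated with a set of reactions via GPRs
#'
#' The union of leaf genes over the reactions' GPR rules; genes occurring
#' under an odd number of `NOT` operators are flagged as inhibitors.
#'
#' @param model a `stoich_model`.
#' @param reaction_ids character vector of reaction ids.
#' @return a tibble with `gene` and `inhibitor`, one row per gene (a gene
#'   appearing both plainly and negated keeps `inhibitor = TRUE`).
#' @export
genes_for_reactions <- function(model, reaction_ids) {
  stopifnot(inherits(model, "stoich_model"))
  i <- match(reaction_ids, model$reactions$id)
  if (anyNA(i)) stop("unknown reactions: ",
                     paste(reaction_ids[is.na(i)], collapse = ", "),
                     call. = FALSE)
  rules <- model$reactions$gpr[i]
  rules <- rules[!is.na(rules) & nzchar(rules)]
  if (length(rules) == 0L) {
    return(tibble::tibble(gene = character(), inhibitor = logical()))
  }
  all <- dplyr::bind_rows(lapply(rules, gpr_genes))
  all |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(inhibitor = any(.data$inhibitor), .groups = "drop") |>
    dplyr::arrange(.data$gene)
}
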