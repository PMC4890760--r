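#' Minimal-cardinality bound relaxation (mixed-integer program)
#'
#' Finds the smallest set of candidate reactions whose bounds must be relaxed
#' for the network to admit a steady-state flux vector. The program is
#'
#' \deqn{\min \sum_{j \in R_r} y_j}
#' subject to \eqn{S v = 0}; \eqn{l_j - n_j \le v_j \le u_j + p_j} for
#' candidates \eqn{j \in R_r}; \eqn{l_i \le v_i \le u_i} for all remaining
#' reactions \eqn{R_n}; \eqn{p_j, n_j \le M y_j}; \eqn{p_j, n_j \ge 0};
#' \eqn{y_j \in \{0, 1\}}. It is solved exactly by branch-and-bound over the
#' binary indicators with convex feasibility subproblems (quadprog) at each
#' node and an LP relaxation bound. Among equal-cardinality optima the result
#' minimizes the total relaxation amount \eqn{\sum_j (p_j + n_j)}, with
#' remaining ties broken lexicographically by reaction id, so output is
#' deterministic.
#'
#' @param model a `stoich_model`. Candidate reactions are expected to carry
#'   the bounds that may be relaxed (typically `[0, 0]` for candidate
#'   exchanges).
#' @param candidates character vector of reaction ids whose bounds may be
#'   relaxed (\eqn{R_r}).
#' @param forced_lower lower bound imposed on all *internal, non-candidate*
#'   reactions for the solve (default 1 AU, forcing every internal reaction
#'   to carry flux so blocked reactions surface); `NULL` leaves bounds as-is.
#' @param big_M the big-M constant bounding relaxation amounts (default 1000).
#' @return a `relaxation_result`: fields `relaxed` (ids with \eqn{y_j = 1}),
#'   `p`, `n` (named relaxation amounts), `v` (achieved flux), `objective`
#'   (the cardinality), plus solve metadata. See [tidy.relaxation_result()].
#' @seealso [add_minimal_exchanges()] which uses this to close dead ends.
#' @export
relax_rxns <- function(model, candidates, forced_lower = 1, big_M = 1000) {
  stopifnot(inherits(model, "stoich_model"), big_M > 0)
  rx <- model$reactions
  miss <- setdiff(candidates, rx$id)
  if (length(miss)) stop("unknown candidate reactions: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cand_idx <- match(candidates, rx$id)
  S <- model$S
  l <- rx$lower_bound
  u <- rx$upper_bound
  if (!is.null(forced_lower)) {
    forced <- rx$kind == "internal" & !rx$id %in% candidates
    l[forced] <- forced_lower
  }

  feas <- function(set_idx) {
    b <- relaxed_bounds(l, u, set_idx, big_M)
    qp_nearest_flux(S, b$l, b$u)
  }

  if (feas(integer(0))$feasible) {
    return(new_relaxation_result(model, character(0), l, u, big_M,
                                 forced_lower))
  }
  all_res <- feas(cand_idx)
  if (!all_res$feasible) {
    de <- find_dead_ends(model)
    stop("network admits no steady state even with every candidate relaxed; ",
         "one-sided species: ",
         if (length(de)) paste(de, collapse = ", ") else "(none detected)",
         call. = FALSE)
  }

  # order candidates by how badly the unrelaxed bounds are violated in the
  # all-relaxed nearest flux; the most-violated are branched on first
  viol <- pmax(all_res$v[cand_idx] - u[cand_idx],
               l[cand_idx] - all_res$v[cand_idx], 0)
  ord <- cand_idx[order(-viol, rx$id[cand_idx])]

  # greedy irreducible incumbent: drop least-violated candidates first
  inc <- ord
  for (j in rev(inc)) {
    trial <- setdiff(inc, j)
    if (feas(trial)$feasible) inc <- trial
  }
  best_k <- length(inc)
  sols <- list(sort(inc))

  lp_bound <- function(included, free) {
    # LP relaxation over the free indicators; a valid lower bound on the
    # number of additional relaxations needed
    nf <- length(free)
    r <- ncol(S)
    Sr <- independent_rows(S)
    nv <- r + nf                             # v then y_free
    A <- matrix(0, nrow(Sr) + 2 * nf, nv)
    b <- numeric(nrow(A)); dir <- character(nrow(A))
    A[seq_len(nrow(Sr)), seq_len(r)] <- Sr
    dir[seq_len(nrow(Sr))] <- "="
    lb <- l; ub <- u
    wide <- relaxed_bounds(lb, ub, included, big_M)
    lb <- wide$l; ub <- wide$u
    lb[free] <- l[free] - big_M; ub[free] <- u[free] + big_M
    for (k in seq_len(nf)) {
      j <- free[k]
      i1 <- nrow(Sr) + 2 * k - 1L
      A[i1, j] <- 1; A[i1, r + k] <- -big_M
      b[i1] <- u[j]; dir[i1] <- "<="
      i2 <- i1 + 1L
      A[i2, j] <- -1; A[i2, r + k] <- -big_M
      b[i2] <- -l[j]; dir[i2] <- "<="
    }
    res <- lp_solve(c(numeric(r), rep(1, nf)), A, b, dir,
                    c(lb, numeric(nf)), c(ub, rep(1, nf)))
    if (res$status != "optimal") return(Inf)
    res$objective
  }

  search <- function(included, free) {
    k <- length(included)
    if (k > best_k) return(invisible())
    node <- feas(included)
    if (node$feasible) {
      if (k < best_k) { best_k <<- k; sols <<- list(sort(included)) }
      else if (k == best_k && length(sols) < 200L) {
        sols[[length(sols) + 1L]] <<- sort(included)
      }
      return(invisible())
    }
    if (length(free) == 0L) return(invisible())
    if (!feas(c(included, free))$feasible) return(invisible())
    if (length(free) > 4L) {
      need <- lp_bound(included, free)
      if (k + ceiling(need - 1e-6) > best_k) return(invisible())
    }
    j <- free[1L]
    search(c(included, j), free[-1L])
    search(included, free[-1L])
  }
  search(integer(0), ord)

  sols <- unique(sols[lengths(sols) == best_k])
  scored <- lapply(sols, function(s) relaxation_amounts(S, l, u, s, big_M))
  totals <- vapply(scored, function(z) z$total, numeric(1))
  keys <- vapply(sols, function(s) paste(sort(rx$id[s]), collapse = "|"),
                 character(1))
  pick <- order(totals, keys)[1L]

  new_relaxation_result(model, rx$id[sols[[pick]]], l, u, big_M, forced_lower,
                        scored[[pick]])
}

# For a fixed relaxed set, minimize total relaxation sum(p + n) by LP and
# recover p, n, v. Variables: v (r), then p, n for each relaxed reaction.
#' @noRd
relaxation_amounts <- function(S, l, u, set_idx, big_M) {
  r <- ncol(S)
  ns <- length(set_idx)
  if (ns == 0L) {
    sol <- qp_nearest_flux(S, l, u)
    return(list(p = numeric(0), n = numeric(0), v = sol$v, total = 0))
  }
  Sr <- independent_rows(S)
  nv <- r + 2 * ns
  A <- matrix(0, nrow(Sr) + 2 * ns, nv)
  b <- numeric(nrow(A)); dir <- character(nrow(A))
  A[seq_len(nrow(Sr)), seq_len(r)] <- Sr
  dir[seq_len(nrow(Sr))] <- "="
  for (k in seq_len(ns)) {
    j <- set_idx[k]
    i1 <- nrow(Sr) + 2 * k - 1L        # v_j - p_k <= u_j
    A[i1, j] <- 1; A[i1, r + k] <- -1
    b[i1] <- u[j]; dir[i1] <- "<="
    i2 <- i1 + 1L                      # -v_j - n_k <= -l_j
    A[i2, j] <- -1; A[i2, r + ns + k] <- -1
    b[i2] <- -l[j]; dir[i2] <- "<="
  }
  lb <- l; ub <- u
  wide <- relaxed_bounds(lb, ub, set_idx, big_M)
  res <- lp_solve(c(numeric(r), rep(1, 2 * ns)), A, b, dir,
                  c(wide$l, numeric(2 * ns)), c(wide$u, rep(big_M, 2 * ns)))
  if (res$status != "optimal") {
    stop("internal error: relaxation amount LP infeasible", call. = FALSE)
  }
  v <- stats::setNames(res$x[seq_len(r)], colnames(S))
  p <- stats::setNames(res$x[r + seq_len(ns)], colnames(S)[set_idx])
  n <- stats::setNames(res$x[r + ns + seq_len(ns)], colnames(S)[set_idx])
  p[p < 1e-9] <- 0; n[n < 1e-9] <- 0
  list(p = p, n = n, v = v, total = sum(p) + sum(n))
}

#' @noRd
new_relaxation_result <- function(model, relaxed_ids, l, u, big_M,
                                  forced_lower, amounts = NULL) {
  relaxed_ids <- sort(relaxed_ids)
  if (is.null(amounts)) {
    amounts <- relaxation_amounts(model$S, l, u,
                                  match(relaxed_ids, model$reactions$id),
                                  big_M)
  }
  structure(
    list(relaxed = relaxed_ids, p = amounts$p, n = amounts$n, v = amounts$v,
         objective = length(relaxed_ids), big_M = big_M,
         forced_lower = forced_lower, model = model),
    class = "relaxation_result"
  )
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat("<relaxation_result> objective (relaxed reactions):", x$objective, "\n")
  if (x$objective > 0) {
    cat("  relaxed:", paste(x$relaxed, collapse = ", "), "\n")
    cat("  total relaxation sum(p + n):",
        format(sum(x$p) + sum(x$n)), "\n")
  }
  invisible(x)
}

#' Tidy a relaxation result
#'
#' One row per relaxed reaction with its upper (`p`) and lower (`n`) bound
#' relaxation amounts and achieved flux.
#'
#' @param x a `relaxation_result`.
#' @param ... unused.
#' @return a tibble with columns `reaction_id`, `p`, `n`, `flux`.
#' @export
tidy.relaxation_result <- function(x, ...) {
  tibble::tibble(
    reaction_id = x$relaxed,
    p = unname(x$p[x$relaxed]),
    n = unname(x$n[x$relaxed]),
    flux = unname(x$v[x$relaxed])
  )
}

#' @rdname tidy.relaxation_result
#' @return `glance()`: a one-row tibble with `objective`, `total_relaxation`,
#'   `big_M`, `forced_lower`.
#' @export
glance.relaxation_result <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    total_relaxation = sum(x$p) + sum(x$n),
    big_M = x$big_M,
    forced_lower = if (is.null(x$forced_lower)) NA_real_ else x$forced_lower
  )
}
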