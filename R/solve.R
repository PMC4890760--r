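# Convex subproblems shared by the reconstruction and reversal solvers.
# Steady-state flux polytopes { v : S v = 0, l <= v <= u } are interrogated
# with quadprog (dual active-set; errors cleanly on inconsistent constraints)
# for feasibility and nearest-point queries, and with the in-package simplex
# for linear objectives.

# Rows of S are frequently linearly dependent in mass-balanced networks;
# reduce to an independent row set (the solution set is unchanged) because
# the dual active-set method requires independent equality constraints.
#' @noRd
independent_rows <- function(S) {
  if (nrow(S) == 0L) return(S)
  qr_t <- qr(t(S))
  keep <- sort(qr_t$pivot[seq_len(qr_t$rank)])
  S[keep, , drop = FALSE]
}

# Minimum of ||v - target||^2 over the flux polytope; target NULL means
# min-norm. Returns feasible = FALSE when the polytope is empty.
#' @noRd
qp_nearest_flux <- function(S, l, u, target = NULL, ridge = 1e-10) {
  r <- ncol(S)
  if (is.null(target)) target <- numeric(r)
  Sr <- independent_rows(S)
  Dmat <- diag(2 + ridge, r)
  dvec <- 2 * target
  Amat <- cbind(t(Sr), diag(r), -diag(r))
  bvec <- c(numeric(nrow(Sr)), l, -u)
  ans <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(Sr)),
    error = function(e) NULL
  )
  if (is.null(ans)) return(list(feasible = FALSE, v = NULL, dist2 = Inf))
  v <- ans$solution
  # clean tiny numerical bound violations
  v <- pmin(pmax(v, l), u)
  list(feasible = TRUE, v = stats::setNames(v, colnames(S)),
       dist2 = sum((v - target)^2))
}

#' @noRd
flux_feasible <- function(S, l, u) qp_nearest_flux(S, l, u)$feasible

# Flux variability analysis: min and max of each requested flux over the
# polytope. Used to seed the hit-and-run sampler and to detect degenerate
# (pointlike) flux spaces.
#' @noRd
fva_bounds <- function(S, l, u, which = seq_len(ncol(S))) {
  Sr <- independent_rows(S)
  r <- ncol(S)
  dirs <- rep("=", nrow(Sr))
  out <- matrix(NA_real_, length(which), 2,
                dimnames = list(colnames(S)[which], c("min", "max")))
  pts <- vector("list", 2 * length(which))
  for (k in seq_along(which)) {
    j <- which[k]
    obj <- numeric(r); obj[j] <- 1
    lo <- lp_solve(obj, Sr, numeric(nrow(Sr)), dirs, l, u)
    hi <- lp_solve(obj, Sr, numeric(nrow(Sr)), dirs, l, u, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("flux variability subproblem infeasible", call. = FALSE)
    }
    out[k, ] <- c(lo$objective, hi$objective)
    pts[[2 * k - 1L]] <- lo$x
    pts[[2 * k]] <- hi$x
  }
  list(range = out, points = do.call(rbind, pts))
}

# Bounds with a set of reactions relaxed by the big-M amount on both sides.
#' @noRd
relaxed_bounds <- function(l, u, idx, big_M) {
  l[idx] <- l[idx] - big_M
  u[idx] <- u[idx] + big_M
  list(l = l, u = u)
}
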