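# Dense two-phase simplex for the small linear programs that arise inside the
# reconstruction and reversal solvers (flux variability warm-up, relaxation
# tie-breaks, LP relaxation bounds). Problems here have tens to a few hundred
# variables, all box-bounded, so a dense tableau with Bland's rule is adequate
# and terminates without cycling.

#' Solve a small linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A x (dir) b` and
#' `lb <= x <= ub`. All bounds must be finite: every variable in the flux
#' problems this package solves lives in a bounded box.
#'
#' @param obj numeric objective coefficients.
#' @param A constraint matrix (dense), one row per constraint.
#' @param b right-hand side.
#' @param dir character vector per row: `"="`, `"<="` or `">="`.
#' @param lb,ub variable bounds, finite, recycled to length of `obj`.
#' @param maximize maximize instead of minimize.
#' @param tol feasibility tolerance.
#' @return list with `status` (`"optimal"` or `"infeasible"`), `x`, `objective`.
#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, b, dir, lb = 0, ub = Inf, maximize = FALSE,
                     tol = 1e-9) {
  n <- length(obj)
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve requires finite variable bounds", call. = FALSE)
  }
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  if (is.null(dim(A))) A <- matrix(A, ncol = n)
  stopifnot(ncol(A) == n, nrow(A) == length(b), length(dir) == length(b))
  cc <- if (maximize) -obj else obj

  # Shift to z = x - lb >= 0; fold inequality rows into equalities with slacks,
  # add explicit upper-bound rows z_j + s_j = w_j.
  w <- ub - lb
  b2 <- b - as.vector(A %*% lb)
  m <- nrow(A)
  n_slack_ineq <- sum(dir != "=")
  # columns: z (n) | ineq slacks | ub slacks (n)
  ncols <- n + n_slack_ineq + n
  Arows <- matrix(0, m + n, ncols)
  rhs <- numeric(m + n)
  k <- 0L
  for (i in seq_len(m)) {
    Arows[i, seq_len(n)] <- A[i, ]
    rhs[i] <- b2[i]
    if (dir[i] == "<=") {
      k <- k + 1L
      Arows[i, n + k] <- 1
    } else if (dir[i] == ">=") {
      k <- k + 1L
      Arows[i, n + k] <- -1
    }
  }
  for (j in seq_len(n)) {
    Arows[m + j, j] <- 1
    Arows[m + j, n + n_slack_ineq + j] <- 1
    rhs[m + j] <- w[j]
  }
  # normalize rows to rhs >= 0
  neg <- rhs < 0
  Arows[neg, ] <- -Arows[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]

  nr <- nrow(Arows)
  # artificial variables, one per row; ub-rows could start with their slack
  # basic, but a uniform artificial basis keeps the code simple.
  Tb <- cbind(Arows, diag(nr))
  basis <- ncols + seq_len(nr)
  n_total <- ncol(Tb)

  run_simplex <- function(Tb, rhs, basis, cost, allowed) {
    # Bland's rule; `allowed` marks columns eligible to enter.
    repeat {
      cb <- cost[basis]
      # reduced costs: c_j - cb' B^{-1} a_j ; maintain via explicit solve each
      # iteration (problems are small).
      y <- tryCatch(solve(t(Tb[, basis, drop = FALSE]), cb),
                    error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular"))
      red <- cost - as.vector(t(Tb) %*% y)
      enter_cand <- which(allowed & red < -tol)
      if (length(enter_cand) == 0L) {
        xb <- solve(Tb[, basis, drop = FALSE], rhs)
        return(list(status = "optimal", basis = basis, xb = xb))
      }
      enter <- min(enter_cand)
      Binv_a <- solve(Tb[, basis, drop = FALSE], Tb[, enter])
      xb <- solve(Tb[, basis, drop = FALSE], rhs)
      pos <- which(Binv_a > tol)
      if (length(pos) == 0L) return(list(status = "unbounded"))
      ratios <- xb[pos] / Binv_a[pos]
      rmin <- min(ratios)
      leave_cand <- pos[ratios <= rmin + tol]
      leave <- leave_cand[which.min(basis[leave_cand])]  # Bland tie-break
      basis[leave] <- enter
    }
  }

  # Phase 1
  cost1 <- c(rep(0, ncols), rep(1, nr))
  res1 <- run_simplex(Tb, rhs, basis, cost1, allowed = rep(TRUE, n_total))
  if (res1$status != "optimal") {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  basis <- res1$basis
  xb <- res1$xb
  if (sum(xb[basis > ncols]) > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # Drive basic artificials (at zero) out where possible.
  art_rows <- which(basis > ncols)
  for (rr in art_rows) {
    Binv_row <- solve(Tb[, basis, drop = FALSE])[rr, , drop = FALSE]
    coefs <- as.vector(Binv_row %*% Tb[, seq_len(ncols), drop = FALSE])
    cand <- which(abs(coefs) > 1e-8 & !(seq_len(ncols) %in% basis))
    if (length(cand) > 0L) basis[rr] <- min(cand)
  }

  # Phase 2: artificials may not re-enter
  cost2 <- c(cc, rep(0, ncols - n), rep(0, nr))
  allowed <- c(rep(TRUE, ncols), rep(FALSE, nr))
  res2 <- run_simplex(Tb, rhs, basis, cost2, allowed = allowed)
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  if (res2$status != "optimal") {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  xfull <- numeric(n_total)
  xfull[res2$basis] <- res2$xb
  x <- xfull[seq_len(n)] + lb
  objv <- sum(obj * x)
  list(status = "optimal", x = x, objective = objv)
}
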