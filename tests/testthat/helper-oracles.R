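# Independent oracles used across the suite. These deliberately avoid the
# package's own solver paths: feasibility goes straight to quadprog, GPR
# evaluation is a second, structurally different implementation, and minimal
# relaxation sets come from exhaustive subset enumeration.

# Steady-state feasibility of { Sv = 0, l <= v <= u } via quadprog alone.
oracle_feasible <- function(S, l, u) {
  qr_t <- qr(t(S))
  Sr <- S[sort(qr_t$pivot[seq_len(qr_t$rank)]), , drop = FALSE]
  r <- ncol(S)
  ans <- tryCatch(
    quadprog::solve.QP(diag(2, r), numeric(r),
                       cbind(t(Sr), diag(r), -diag(r)),
                       c(numeric(nrow(Sr)), l, -u), meq = nrow(Sr)),
    error = function(e) NULL
  )
  !is.null(ans)
}

# Exhaustive minimum-cardinality relaxation oracle. Returns the minimum k and
# every optimal candidate subset (by reaction id).
oracle_min_relax <- function(model, candidates, forced_lower = 1,
                             big_M = 1000) {
  rx <- model$reactions
  idx <- match(candidates, rx$id)
  l <- rx$lower_bound; u <- rx$upper_bound
  forced <- rx$kind == "internal" & !rx$id %in% candidates
  l[forced] <- forced_lower
  feas <- function(set) {
    ll <- l; uu <- u
    ll[set] <- ll[set] - big_M
    uu[set] <- uu[set] + big_M
    oracle_feasible(model$S, ll, uu)
  }
  for (k in 0:length(idx)) {
    sets <- if (k == 0) list(integer(0)) else
      utils::combn(idx, k, simplify = FALSE)
    hits <- Filter(feas, sets)
    if (length(hits)) {
      return(list(k = k, sets = lapply(hits, function(s) sort(rx$id[s]))))
    }
  }
  list(k = NA_integer_, sets = list())
}

# Exhaustive reversal oracle: per-subset convex QP, objective
# alpha * ||v - vE|| + (1 - alpha) * |subset|.
oracle_min_distance <- function(model, v_E, alpha, candidates,
                                big_M = 1000) {
  rx <- model$reactions
  idx <- match(candidates, rx$id)
  S <- model$S
  qr_t <- qr(t(S))
  Sr <- S[sort(qr_t$pivot[seq_len(qr_t$rank)]), , drop = FALSE]
  r <- ncol(S)
  qp_dist <- function(set) {
    l <- rx$lower_bound; u <- rx$upper_bound
    l[set] <- l[set] - big_M
    u[set] <- u[set] + big_M
    ans <- tryCatch(
      quadprog::solve.QP(diag(2, r), 2 * as.numeric(v_E),
                         cbind(t(Sr), diag(r), -diag(r)),
                         c(numeric(nrow(Sr)), l, -u), meq = nrow(Sr)),
      error = function(e) NULL
    )
    if (is.null(ans)) return(Inf)
    sqrt(max(sum((pmin(pmax(ans$solution, l), u) - v_E)^2), 0))
  }
  best <- list(obj = Inf, set = NULL, dist = NA)
  for (k in 0:length(idx)) {
    sets <- if (k == 0) list(integer(0)) else
      utils::combn(idx, k, simplify = FALSE)
    for (set in sets) {
      d <- qp_dist(set)
      obj <- alpha * d + (1 - alpha) * k
      if (obj < best$obj - 1e-9) {
        best <- list(obj = obj, set = sort(rx$id[set]), dist = d)
      }
    }
  }
  best
}

# Second, independent GPR evaluator: compiles the rule string into an R
# expression over pmin/pmax and evaluates it.
oracle_gpr_eval <- function(rule, states) {
  eval_node <- function(tokens, pos) {
    parse_or <- function(pos) {
      res <- parse_and(pos)
      while (res$pos <= length(tokens) &&
             toupper(tokens[res$pos]) == "OR") {
        nxt <- parse_and(res$pos + 1L)
        res <- list(val = max(res$val, nxt$val), pos = nxt$pos)
      }
      res
    }
    parse_and <- function(pos) {
      res <- parse_un(pos)
      while (res$pos <= length(tokens) &&
             toupper(tokens[res$pos]) == "AND") {
        nxt <- parse_un(res$pos + 1L)
        res <- list(val = min(res$val, nxt$val), pos = nxt$pos)
      }
      res
    }
    parse_un <- function(pos) {
      tok <- tokens[pos]
      if (toupper(tok) == "NOT") {
        res <- parse_un(pos + 1L)
        return(list(val = -res$val, pos = res$pos))
      }
      if (tok == "(") {
        res <- parse_or(pos + 1L)
        return(list(val = res$val, pos = res$pos + 1L))
      }
      v <- states[tok]
      list(val = if (is.na(v)) 0 else unname(v), pos = pos + 1L)
    }
    parse_or(pos)
  }
  toks <- gsub("\\(", " ( ", gsub("\\)", " ) ", rule))
  toks <- strsplit(trimws(toks), "\\s+")[[1]]
  eval_node(toks, 1L)$val
}

# Random GPR rule generator for round-trip and property tests.
random_gpr <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.4) {
    return(list(op = "gene", gene = sample(genes, 1)))
  }
  op <- sample(c("and", "or", "not"), 1)
  if (op == "not") {
    list(op = "not", args = list(random_gpr(genes, depth - 1)))
  } else {
    k <- sample(2:3, 1)
    list(op = op, args = replicate(k, random_gpr(genes, depth - 1),
                                   simplify = FALSE))
  }
}

# Small reusable toy models -------------------------------------------------

chain_model <- function() {
  stoich_model(tibble::tibble(id = c("R1", "R2"),
                              equation = c("A -> B", "B -> C")))
}

# closed linear pipe: -> A -> B -> (all fluxes equal at steady state)
pipe_model <- function(ub = 10) {
  stoich_model(tibble::tibble(
    id = c("EX_in", "R1", "EX_out"),
    equation = c("-> A", "A -> B", "B ->"),
    lower_bound = 0, upper_bound = ub
  ))
}

# two-path diamond with shared uptake bounded at `ub`
diamond_flux_model <- function(ub = 10) {
  stoich_model(tibble::tibble(
    id = c("EX_in", "R1", "R2", "R3", "R4", "EX_out"),
    equation = c("-> A", "A -> B", "A -> C", "B -> D", "C -> D", "D ->"),
    lower_bound = 0, upper_bound = ub
  ))
}

# random connected acyclic 1-1 network over n species, no exchanges
random_pathway <- function(n, seed) {
  withr::with_seed(seed, {
    sp <- sprintf("S%02d", seq_len(n))
    edges <- cbind(seq_len(n - 1), 2:n)
    extra <- which(upper.tri(matrix(0, n, n)) & stats::runif(n * n) < 0.2,
                   arr.ind = TRUE)
    extra <- extra[extra[, 2] - extra[, 1] > 1, , drop = FALSE]
    edges <- unique(rbind(edges, extra))
    stoich_model(tibble::tibble(
      id = sprintf("R%02d", seq_len(nrow(edges))),
      equation = paste(sp[edges[, 1]], "->", sp[edges[, 2]])
    ))
  })
}

# model with candidate exchanges for every species at [0, 0], ready for
# relax_rxns
with_candidate_exchanges <- function(model) {
  sp <- model$species$id
  cand <- tibble::tibble(
    id = paste0("EXC_", sp), equation = paste("->", sp),
    lower_bound = 0, upper_bound = 0
  )
  list(model = fluxtalk:::add_reactions(model, cand), candidates = cand$id)
}
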