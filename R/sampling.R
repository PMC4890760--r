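#' Sample the steady-state flux space of a model
#'
#' Draws flux vectors approximately uniformly from the polytope
#' `{ v : S v = 0, l <= v <= u }` with an artificially-centered hit-and-run
#' walk. Warm-up points come from flux variability analysis (the min/max
#' vertex of every reaction), so every candidate direction lies in the null
#' space of S and each iterate satisfies steady state to machine precision.
#' The walk keeps a running center; each step picks a random warm-up point,
#' moves along the chord through the current point in that direction, and
#' draws the step uniformly from the feasible segment. Every `thinning`-th
#' iterate is recorded. Degenerate (pointlike) flux spaces yield constant
#' samples.
#'
#' @param model a feasible `stoich_model`.
#' @param n_samples number of recorded samples (default 5000).
#' @param seed integer seed; the run is deterministic given the seed.
#' @param thinning record every `thinning`-th step (default 100).
#' @return a `flux_samples` object: `samples` (n_samples x r matrix, AU),
#'   `reaction_ids`, `seed`, `method`.
#' @export
sample_fluxes <- function(model, n_samples = 5000, seed = 1, thinning = 100) {
  stopifnot(inherits(model, "stoich_model"), n_samples >= 1, thinning >= 1)
  S <- model$S
  l <- model$reactions$lower_bound
  u <- model$reactions$upper_bound
  if (!flux_feasible(S, l, u)) {
    stop("model is infeasible: no steady-state flux satisfies the bounds",
         call. = FALSE)
  }
  r <- ncol(S)
  fva <- fva_bounds(S, l, u)
  span <- fva$range[, "max"] - fva$range[, "min"]
  warm <- unique(round(fva$points, 12))
  center <- colMeans(warm)

  samples <- matrix(NA_real_, n_samples, r,
                    dimnames = list(NULL, colnames(S)))
  if (all(span < 1e-9) || nrow(warm) < 2L) {
    samples[] <- rep(center, each = n_samples)
  } else {
    # periodic re-projection onto { Sv = 0 } keeps accumulated rounding
    # error of the long walk well below the steady-state tolerance
    Sr <- independent_rows(S)
    proj <- t(Sr) %*% solve(Sr %*% t(Sr))
    withr::with_seed(seed, {
      x <- center
      run_center <- center
      n_seen <- nrow(warm)
      recorded <- 0L
      step <- 0L
      eps <- 1e-12
      while (recorded < n_samples) {
        step <- step + 1L
        if (step %% 500L == 0L) {
          x <- x - as.vector(proj %*% (Sr %*% x))
          x <- pmin(pmax(x, l), u)
          x <- x - as.vector(proj %*% (Sr %*% x))
        }
        w <- warm[sample.int(nrow(warm), 1L), ]
        d <- w - run_center
        nd <- sqrt(sum(d^2))
        if (nd < 1e-10) next
        d <- d / nd
        # feasible segment along d within the box (S d = 0 by construction)
        tmax <- Inf; tmin <- -Inf
        nz <- which(abs(d) > 1e-12)
        hi <- (u[nz] - x[nz]) / d[nz]
        lo <- (l[nz] - x[nz]) / d[nz]
        tmax <- min(pmax(hi, lo))
        tmin <- max(pmin(hi, lo))
        if (!is.finite(tmax) || !is.finite(tmin) || tmax - tmin < 1e-10) next
        t <- stats::runif(1, tmin + eps, tmax - eps)
        x <- x + t * d
        n_seen <- n_seen + 1L
        run_center <- run_center + (x - run_center) / n_seen
        if (step %% thinning == 0L) {
          recorded <- recorded + 1L
          samples[recorded, ] <- x
        }
      }
    })
  }
  res <- max(abs(S %*% t(samples)))
  if (res > 1e-6) {
    stop("sampler drifted off the steady-state manifold (residual ",
         format(res), ")", call. = FALSE)
  }
  structure(
    list(samples = samples, reaction_ids = colnames(S),
         kind = model$reactions$kind, seed = seed, thinning = thinning,
         method = "achr"),
    class = "flux_samples"
  )
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("<flux_samples> ", nrow(x$samples), " samples x ", ncol(x$samples),
      " reactions (", x$method, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Per-reaction mean flux of a sample set
#'
#' @param samples a `flux_samples`.
#' @return a tibble with `reaction_id` and `mean_flux` (AU).
#' @export
mean_flux <- function(samples) {
  stopifnot(inherits(samples, "flux_samples"), nrow(samples$samples) >= 1)
  tibble::tibble(
    reaction_id = samples$reaction_ids,
    mean_flux = unname(colMeans(samples$samples))
  )
}

#' Tidy flux samples into long form
#' @param x a `flux_samples`.
#' @param ... unused.
#' @return a tibble with `sample`, `reaction_id`, `flux`.
#' @export
tidy.flux_samples <- function(x, ...) {
  tibble::tibble(
    sample = rep(seq_len(nrow(x$samples)), times = ncol(x$samples)),
    reaction_id = rep(x$reaction_ids, each = nrow(x$samples)),
    flux = as.vector(x$samples)
  )
}

#' Compare two context models' sampled flux distributions
#'
#' Per reaction, computes the mean flux in each condition, the mesenchymal /
#' epithelial fold change `(mean_M + epsilon) / (mean_E + epsilon)`, its
#' log2, the linear difference `mean_M - mean_E`, and the span statistic in
#' each condition with its ratio. Fold changes above 1 (log2 positive) mean
#' higher flux in the mesenchymal model; negative log2 values mean higher
#' flux in the epithelial model. The span statistic defaults to the mean
#' flux; `span = "width"` uses the max - min width of the sampled
#' distribution instead.
#'
#' @param set_E,set_M `flux_samples` of the paired models over the same
#'   reactions.
#' @param epsilon small AU offset guarding ratios of zero-flux reactions.
#' @param span `"mean"` or `"width"`.
#' @return a `flux_comparison` tibble: `reaction_id`, `kind`, `mean_E`,
#'   `mean_M`, `fold`, `log2_fold`, `diff`, `span_E`, `span_M`, `span_ratio`.
#' @export
compare_fluxes <- function(set_E, set_M, epsilon = 1e-6,
                           span = c("mean", "width")) {
  span <- match.arg(span)
  stopifnot(inherits(set_E, "flux_samples"), inherits(set_M, "flux_samples"))
  if (!identical(set_E$reaction_ids, set_M$reaction_ids)) {
    stop("sample sets are over different reaction sets", call. = FALSE)
  }
  m_E <- colMeans(set_E$samples)
  m_M <- colMeans(set_M$samples)
  span_of <- function(s) {
    if (span == "mean") colMeans(s$samples)
    else apply(s$samples, 2, function(col) max(col) - min(col))
  }
  s_E <- span_of(set_E); s_M <- span_of(set_M)
  fold <- (m_M + epsilon) / (m_E + epsilon)
  out <- tibble::tibble(
    reaction_id = set_E$reaction_ids,
    kind = set_E$kind,
    mean_E = unname(m_E), mean_M = unname(m_M),
    fold = unname(fold), log2_fold = log2(unname(fold)),
    diff = unname(m_M - m_E),
    span_E = unname(s_E), span_M = unname(s_M),
    span_ratio = unname((s_M + epsilon) / (s_E + epsilon))
  )
  class(out) <- c("flux_comparison", class(out))
  attr(out, "span") <- span
  attr(out, "epsilon") <- epsilon
  out
}

#' Kernel density estimate of a reaction's sampled flux
#'
#' Gaussian kernel with Silverman's bandwidth, for reporting flux
#' distributions; the reported `mode` is the most probable flux. A
#' zero-variance column is returned as a degenerate single-point spike
#' rather than an error.
#'
#' @param samples a `flux_samples` with at least 30 samples.
#' @param reaction_id which reaction.
#' @return a tibble with `flux`, `density`; attributes `mode` (most probable
#'   flux) and `degenerate`.
#' @export
density_estimate <- function(samples, reaction_id) {
  stopifnot(inherits(samples, "flux_samples"))
  if (nrow(samples$samples) < 30) {
    stop("need at least 30 samples for a density estimate", call. = FALSE)
  }
  j <- match(reaction_id, samples$reaction_ids)
  if (is.na(j)) stop("unknown reaction: ", reaction_id, call. = FALSE)
  x <- samples$samples[, j]
  if (stats::sd(x) < 1e-12) {
    out <- tibble::tibble(flux = x[1], density = Inf)
    attr(out, "mode") <- x[1]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d <- stats::density(x, kernel = "gaussian", bw = "nrd0")
  out <- tibble::tibble(flux = d$x, density = d$y)
  attr(out, "mode") <- d$x[which.max(d$y)]
  attr(out, "degenerate") <- FALSE
  out
}

#' Aggregate a flux comparison over named pathways
#'
#' For each pathway (a named set of reaction ids), reports the per-pathway
#' aggregate fold change (geometric mean of per-reaction folds by default)
#' together with per-reaction rows, and exposes a heat-map-ready log2 fold
#' matrix via `attr(, "log2_matrix")`. Exchange reactions are excluded by
#' default, matching how such pathway summaries are usually displayed.
#'
#' @param comparison a `flux_comparison`.
#' @param pathway_sets named list: pathway -> character vector of reaction
#'   ids.
#' @param include_exchanges keep exchange reactions (default FALSE)?
#' @param aggregate `"geometric"` (default) or `"arithmetic"` mean of folds.
#' @return a `pathway_report` tibble: `pathway`, `n_reactions`,
#'   `aggregate_fold`, `log2_aggregate`.
#' @export
pathway_report <- function(comparison, pathway_sets,
                           include_exchanges = FALSE,
                           aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(comparison, "flux_comparison"),
            is.list(pathway_sets), length(pathway_sets) > 0,
            !is.null(names(pathway_sets)))
  rows <- list(); mat_rows <- list()
  for (pw in names(pathway_sets)) {
    ids <- pathway_sets[[pw]]
    if (length(ids) == 0L) stop("empty pathway set: ", pw, call. = FALSE)
    miss <- setdiff(ids, comparison$reaction_id)
    if (length(miss)) stop("pathway '", pw, "' references unknown reactions: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    sub <- comparison[comparison$reaction_id %in% ids, ]
    if (!include_exchanges) sub <- sub[sub$kind != "exchange", ]
    if (nrow(sub) == 0L) stop("pathway '", pw,
                              "' has no internal reactions to aggregate",
                              call. = FALSE)
    agg <- if (aggregate == "geometric") exp(mean(log(sub$fold)))
           else mean(sub$fold)
    rows[[pw]] <- tibble::tibble(pathway = pw, n_reactions = nrow(sub),
                                 aggregate_fold = agg,
                                 log2_aggregate = log2(agg))
    mat_rows[[pw]] <- stats::setNames(sub$log2_fold, sub$reaction_id)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pathway_report", class(out))
  all_ids <- unique(unlist(lapply(mat_rows, names)))
  mat <- matrix(NA_real_, length(mat_rows), length(all_ids),
                dimnames = list(names(mat_rows), all_ids))
  for (pw in names(mat_rows)) mat[pw, names(mat_rows[[pw]])] <- mat_rows[[pw]]
  attr(out, "log2_matrix") <- mat
  attr(out, "aggregate") <- aggregate
  out
}
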