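test_that("a linear pipe forces all fluxes equal in every sample", {
  s <- sample_fluxes(pipe_model(ub = 10), n_samples = 200, seed = 1,
                     thinning = 5)
  expect_equal(ncol(s$samples), 3)
  spread <- apply(s$samples, 1, function(v) max(v) - min(v))
  expect_lt(max(spread), 1e-8)
  expect_true(all(s$samples >= -1e-9 & s$samples <= 10 + 1e-9))
})

test_that("sampling is deterministic given the seed", {
  m <- diamond_flux_model()
  a <- sample_fluxes(m, n_samples = 100, seed = 42, thinning = 5)
  b <- sample_fluxes(m, n_samples = 100, seed = 42, thinning = 5)
  expect_identical(a$samples, b$samples)
  c <- sample_fluxes(m, n_samples = 100, seed = 43, thinning = 5)
  expect_false(identical(a$samples, c$samples))
})

test_that("all samples satisfy steady state and bounds", {
  withr::with_seed(3, {
    for (i in 1:5) {
      net <- make_network(synthetic_spec(n_species = sample(4:7, 1),
                                         topology = "random-dag", seed = i))
      m <- add_minimal_exchanges(convert_pathway(net$pathway))
      s <- sample_fluxes(m, n_samples = 200, seed = i, thinning = 5)
      expect_lt(max(abs(m$S %*% t(s$samples))), 1e-6)
      l <- m$reactions$lower_bound; u <- m$reactions$upper_bound
      expect_true(all(t(s$samples) >= l - 1e-7))
      expect_true(all(t(s$samples) <= u + 1e-7))
    }
  })
})

test_that("diamond path means match a rejection-sampling oracle", {
  # polytope in (v_R1, v_R2): square [0,10]^2 cut by v_R1 + v_R2 <= 10;
  # uniform over that triangle gives E[v_R1] = E[v_R2] = 10/3
  m <- diamond_flux_model(ub = 10)
  s <- sample_fluxes(m, n_samples = 4000, seed = 7, thinning = 20)
  mf <- mean_flux(s)
  withr::with_seed(99, {
    pts <- matrix(stats::runif(2e5, 0, 10), ncol = 2)
    pts <- pts[rowSums(pts) <= 10, ]
    oracle_mean <- colMeans(pts)
  })
  # batch-means standard error of the (autocorrelated) chain
  se_of <- function(x) {
    bm <- tapply(x, rep(1:40, each = length(x) / 40), mean)
    stats::sd(bm) / sqrt(length(bm))
  }
  for (k in 1:2) {
    rid <- c("R1", "R2")[k]
    est <- mf$mean_flux[mf$reaction_id == rid]
    se <- se_of(s$samples[, rid])
    expect_lt(abs(est - oracle_mean[k]), 3 * se + 0.05)
  }
})

test_that("mean_flux matches direct recomputation", {
  m <- diamond_flux_model()
  s <- sample_fluxes(m, n_samples = 50, seed = 2, thinning = 2)
  mf <- mean_flux(s)
  for (j in seq_along(mf$reaction_id)) {
    expect_equal(mf$mean_flux[j], sum(s$samples[, j]) / nrow(s$samples))
  }
})

test_that("compare_fluxes computes folds, log2 and spans as specified", {
  fake <- function(mat, ids) {
    structure(list(samples = mat, reaction_ids = ids,
                   kind = rep("internal", length(ids)),
                   seed = 0, thinning = 1, method = "manual"),
              class = "flux_samples")
  }
  sE <- fake(cbind(c(2, 2), c(0, 10)), c("Ra", "Rb"))
  sM <- fake(cbind(c(4, 4), c(5, 5)), c("Ra", "Rb"))
  cmp <- compare_fluxes(sE, sM)
  expect_equal(cmp$fold[1], 2, tolerance = 1e-5)
  expect_equal(cmp$log2_fold[1], 1, tolerance = 1e-5)
  expect_equal(cmp$diff[1], 2)
  expect_equal(cmp$mean_E[2], 5)     # column {0, 10} averages to 5
  expect_equal(cmp$span_ratio[2], 1, tolerance = 1e-5)
  w <- compare_fluxes(sE, sM, span = "width")
  expect_equal(w$span_E[2], 10)
  expect_equal(w$span_M[2], 0)

  identical_cmp <- compare_fluxes(sE, sE)
  expect_true(all(abs(identical_cmp$log2_fold) < 1e-12))
  expect_true(all(identical_cmp$fold == 1))

  sX <- fake(cbind(c(1, 1)), "other")
  expect_error(compare_fluxes(sE, sX), "different reaction sets")
})

test_that("resampling the same model stays within sampling noise", {
  m <- diamond_flux_model()
  a <- sample_fluxes(m, n_samples = 2000, seed = 1, thinning = 10)
  b <- sample_fluxes(m, n_samples = 2000, seed = 2, thinning = 10)
  cmp <- compare_fluxes(a, b)
  # bootstrap CI of the log2 fold under the null of identical polytopes
  for (j in seq_along(cmp$reaction_id)) {
    boots <- replicate(200, {
      ia <- sample.int(2000, replace = TRUE)
      ib <- sample.int(2000, replace = TRUE)
      log2((mean(b$samples[ib, j]) + 1e-6) /
             (mean(a$samples[ia, j]) + 1e-6))
    })
    # generous multiple of the bootstrap spread: chains are autocorrelated
    expect_lt(abs(cmp$log2_fold[j]), 10 * stats::sd(boots) + 0.05)
  }
})

test_that("shrinking an upper bound 100-fold never raises the mean", {
  withr::with_seed(23, {
    for (i in 1:4) {
      net <- make_network(synthetic_spec(n_species = 5,
                                         topology = "random-dag",
                                         seed = 40 + i))
      m <- add_minimal_exchanges(convert_pathway(net$pathway))
      internal <- m$reactions$id[m$reactions$kind == "internal"]
      target <- sample(internal, 1)
      s0 <- sample_fluxes(m, n_samples = 1500, seed = i, thinning = 5)
      m2 <- fluxtalk:::set_bounds(
        m, target,
        upper = m$reactions$upper_bound[m$reactions$id == target] / 100)
      s1 <- sample_fluxes(m2, n_samples = 1500, seed = i + 50, thinning = 5)
      mu0 <- mean(s0$samples[, target])
      mu1 <- mean(s1$samples[, target])
      se <- stats::sd(s0$samples[, target]) / sqrt(150)  # effective n guess
      expect_lt(mu1, mu0 + 2 * se)
    }
  })
})

test_that("density estimates behave on known distributions", {
  fake <- function(x) {
    structure(list(samples = matrix(x, ncol = 1,
                                    dimnames = list(NULL, "R")),
                   reaction_ids = "R", kind = "internal", seed = 0,
                   thinning = 1, method = "manual"),
              class = "flux_samples")
  }
  # constant column: degenerate spike, not a crash
  d0 <- density_estimate(fake(rep(5, 100)), "R")
  expect_true(attr(d0, "degenerate"))
  expect_equal(attr(d0, "mode"), 5)

  withr::with_seed(8, {
    dn <- density_estimate(fake(stats::rnorm(5000)), "R")
    expect_false(attr(dn, "degenerate"))
    expect_lt(abs(attr(dn, "mode")), 0.2)
    # curve integrates to ~1 on its grid
    grid <- dn$flux
    expect_equal(sum(dn$density) * (grid[2] - grid[1]), 1, tolerance = 1e-2)

    du <- density_estimate(fake(stats::runif(5000, 0, 10)), "R")
    central <- du$flux >= 1 & du$flux <= 9
    expect_true(all(abs(du$density[central] - 0.1) < 0.02))
  })
  expect_error(density_estimate(fake(rep(1, 10)), "R"), "30 samples")
})

test_that("pathway aggregation uses the geometric mean of folds", {
  fake <- function(mat, ids, kind) {
    structure(list(samples = mat, reaction_ids = ids, kind = kind,
                   seed = 0, thinning = 1, method = "manual"),
              class = "flux_samples")
  }
  ids <- c("Ra", "Rb", "EXc")
  kind <- c("internal", "internal", "exchange")
  sE <- fake(cbind(c(2, 2), c(4, 4), c(1, 1)), ids, kind)
  sM <- fake(cbind(c(4, 4), c(2, 2), c(9, 9)), ids, kind)
  cmp <- compare_fluxes(sE, sM)
  rep1 <- pathway_report(cmp, list(P1 = "Ra"))
  expect_equal(rep1$aggregate_fold, 2, tolerance = 1e-5)
  # folds {2, 0.5} have geometric mean 1
  rep2 <- pathway_report(cmp, list(P = c("Ra", "Rb")))
  expect_equal(rep2$aggregate_fold, 1, tolerance = 1e-5)
  # exchange reactions are excluded from the matrix by default
  rep3 <- pathway_report(cmp, list(P = c("Ra", "EXc")))
  expect_equal(rep3$n_reactions, 1)
  expect_false("EXc" %in% colnames(attr(rep3, "log2_matrix")))
  expect_error(pathway_report(cmp, list(P = character(0))), "empty")
  expect_error(pathway_report(cmp, list(P = "nope")), "unknown")
})

test_that("an infeasible model is rejected before sampling", {
  m <- convert_pathway(chain_model())  # dead ends, no exchanges
  m$reactions$lower_bound <- 1
  expect_error(suppressWarnings(sample_fluxes(m, 10, seed = 1)),
               "infeasible")
})
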