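test_that("a reachable target needs no relaxation", {
  m <- pipe_model(ub = 10)
  v_E <- stats::setNames(c(4, 4, 4), m$reactions$id)
  rt <- minimize_distance(m, v_E, alpha = 0.5)
  expect_length(rt$relaxed, 0)
  expect_equal(rt$distance, 0, tolerance = 1e-5)
  expect_equal(unname(rt$v), c(4, 4, 4), tolerance = 1e-5)
})

test_that("the one-dimensional trade-off matches the closed form", {
  # pipe with ub 10, target flux 20 everywhere. Relaxing zero reactions
  # leaves v = 10 (distance sqrt(3)*10); relaxing all three reaches the
  # target exactly at cardinality cost 3. Closed-form objectives:
  #   none:  alpha * sqrt(300)
  #   all:   (1 - alpha) * 3
  # (relaxing only a subset cannot beat these: flux stays coupled)
  m <- pipe_model(ub = 10)
  v_E <- stats::setNames(c(20, 20, 20), m$reactions$id)

  rt_lo <- minimize_distance(m, v_E, alpha = 0.01)
  expect_length(rt_lo$relaxed, 0)
  expect_equal(rt_lo$distance, sqrt(300), tolerance = 1e-4)

  rt_hi <- minimize_distance(m, v_E, alpha = 0.99)
  expect_length(rt_hi$relaxed, 3)
  expect_equal(rt_hi$distance, 0, tolerance = 1e-4)
  expect_equal(unname(rt_hi$v), c(20, 20, 20), tolerance = 1e-4)

  # crossover where alpha * sqrt(300) = (1 - alpha) * 3
  a_star <- 3 / (sqrt(300) + 3)
  for (a in c(a_star - 0.02, a_star + 0.02)) {
    rt <- minimize_distance(m, v_E, alpha = a)
    closed_form <- min(a * sqrt(300), (1 - a) * 3)
    expect_equal(rt$objective, closed_form, tolerance = 1e-4)
  }
})

test_that("branch-and-bound matches enumeration and the exhaustive oracle", {
  withr::with_seed(29, {
    for (i in 1:6) {
      net <- make_network(synthetic_spec(n_species = sample(4:6, 1),
                                         topology = "random-dag",
                                         seed = 60 + i))
      m <- add_minimal_exchanges(convert_pathway(net$pathway))
      cand <- m$reactions$id
      if (length(cand) > 10) cand <- sample(cand, 10)
      s <- sample_fluxes(m, n_samples = 200, seed = i, thinning = 5)
      v_E <- stats::setNames(colMeans(s$samples) *
                               stats::runif(ncol(s$samples), 0.5, 3),
                             m$reactions$id)
      alpha <- stats::runif(1, 0.2, 0.9)
      bnb <- minimize_distance(m, v_E, alpha = alpha, candidates = cand)
      enu <- minimize_distance(m, v_E, alpha = alpha, candidates = cand,
                               method = "enumerate")
      orc <- oracle_min_distance(m, v_E, alpha, cand)
      expect_equal(bnb$objective, orc$obj, tolerance = 1e-5,
                   info = paste("net", i))
      expect_equal(enu$objective, orc$obj, tolerance = 1e-5)
      expect_identical(sort(bnb$relaxed), sort(enu$relaxed))
    }
  })
})

test_that("achieved distance is non-increasing in alpha", {
  m <- pipe_model(ub = 10)
  v_E <- stats::setNames(c(25, 25, 25), m$reactions$id)
  dists <- vapply(seq(0.05, 0.95, by = 0.15), function(a) {
    minimize_distance(m, v_E, alpha = a)$distance
  }, numeric(1))
  expect_true(all(diff(dists) <= 1e-6))
})

test_that("alpha = 0 recovers the pure cardinality objective", {
  m <- pipe_model(ub = 10)
  v_E <- stats::setNames(c(20, 20, 20), m$reactions$id)
  rt <- minimize_distance(m, v_E, alpha = 0)
  expect_length(rt$relaxed, 0)   # feasibility needs nothing relaxed
  expect_equal(rt$objective, 0)
  expect_error(minimize_distance(m, v_E, alpha = 1.2), "alpha")
})

test_that("relaxed reactions map to their GPR genes with inhibitor flags", {
  m <- stoich_model(tibble::tibble(
    id = c("R1", "R2", "R3"),
    equation = c("A -> B", "B -> C", "C -> D"),
    gpr = c("g1 AND g2", "NOT g3", NA)
  ))
  g <- genes_for_reactions(m, c("R1", "R2"))
  expect_setequal(g$gene, c("g1", "g2", "g3"))
  expect_identical(g$inhibitor[g$gene == "g3"], TRUE)
  expect_false(any(g$inhibitor[g$gene %in% c("g1", "g2")]))
  expect_equal(nrow(genes_for_reactions(m, "R3")), 0)
  expect_error(genes_for_reactions(m, "Rx"), "unknown")
})

test_that("reversal on a planted context pair recovers tightened reactions", {
  withr::with_seed(37, {
    net <- make_network(synthetic_spec(n_species = 6, topology = "diamond",
                                       n_modifiers = 2, n_inhibitors = 1,
                                       seed = 7))
    m <- add_minimal_exchanges(
      build_gprs(insert_modifiers(convert_pathway(net$pathway))))
    genes <- model_genes(m)
    sp2 <- synthetic_spec(n_species = 6, topology = "diamond",
                          n_modifiers = 2, n_inhibitors = 1, seed = 7,
                          planted_up_E = genes[1])
    ex <- make_expression(sp2, m)
    rcalls <- propagate_to_reactions(m, classify_regulation(ex$table, 2))
    planted_rxns <- rcalls$reaction_id[rcalls$state == "up_E"]
    pair <- build_context_pair(m, rcalls)
    v_E <- mean_flux(sample_fluxes(pair$model_E, 1000, seed = 5,
                                   thinning = 10))
    rt <- minimize_distance(pair$model_M, v_E, alpha = 0.9)
    # the tightened reactions are exactly what must be relaxed to reach v_E
    expect_setequal(rt$relaxed, planted_rxns)
    expect_true(genes[1] %in% rt$genes$gene)
  })
})
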