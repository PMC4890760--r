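test_that("predicted direction follows the sign and the pathway fold", {
  st <- tibble::tibble(gene_id = c("GAPDH", "G6PC"), pathway = "AKT",
                       sign = c(1, -1))
  # pathway carries more flux in the epithelial model
  p <- predict_metabolic_expression(st, pathway_fold = 0.5)
  expect_identical(p$predicted, c("down_in_M", "down_in_E"))
  # mirror image when the mesenchymal model has more flux
  p2 <- predict_metabolic_expression(st, pathway_fold = 2)
  expect_identical(p2$predicted, c("down_in_E", "down_in_M"))
  # a fold of exactly 1 yields no call
  p3 <- predict_metabolic_expression(st, pathway_fold = 1)
  expect_true(all(is.na(p3$predicted)))
  expect_error(predict_metabolic_expression(st, 0), "pathway_fold > 0")
  expect_error(
    predict_metabolic_expression(tibble::tibble(gene_id = "x", sign = 2),
                                 0.5), "\\+1 or -1")
})

test_that("agreement scoring counts exact matches and excludes NA", {
  pred <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                         predicted = rep("down_in_M", 4))
  obs <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        observed = c("down_in_M", "down_in_M", "down_in_M",
                                     "down_in_M"))
  g <- glance(score_agreement(pred, obs))
  expect_equal(g$n_evaluable, 4)
  expect_equal(g$percent_agree, 100)

  obs$observed[2] <- NA
  obs$observed[3] <- "down_in_E"
  g2 <- glance(score_agreement(pred, obs))
  expect_equal(g2$n_evaluable, 3)
  expect_equal(g2$n_agree, 2)
  expect_identical(g2$disagreeing, "c")
})

test_that("agreement scoring matches an independent recount on random data", {
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(5:30, 1)
      genes <- sprintf("g%d", seq_len(n))
      pred <- tibble::tibble(
        gene_id = genes,
        predicted = sample(c("down_in_M", "down_in_E"), n, replace = TRUE))
      obs <- tibble::tibble(
        gene_id = genes,
        observed = sample(c("down_in_M", "down_in_E", NA), n,
                          replace = TRUE))
      g <- glance(score_agreement(pred, obs))
      # counting oracle
      joined <- merge(pred, obs, by = "gene_id")
      ev <- !is.na(joined$observed)
      expect_equal(g$n_evaluable, sum(ev))
      expect_equal(g$n_agree,
                   sum(ev & joined$predicted == joined$observed, na.rm = TRUE))
      if (g$n_evaluable > 0) {
        expect_equal(g$percent_agree, 100 * g$n_agree / g$n_evaluable)
      }
    }
  })
})

test_that("printed percentages truncate toward zero at one decimal", {
  expect_equal(fluxtalk:::trunc1(100 * 13 / 15), 86.6)
  expect_equal(fluxtalk:::trunc1(100 * 2 / 15), 13.3)
})

test_that("metabolic constraining tightens exactly the directed reactions", {
  met <- stoich_model(tibble::tibble(
    id = c("HEX", "PGI", "EX_glc", "EX_f6p"),
    equation = c("glc -> g6p", "g6p -> f6p", "-> glc", "f6p ->"),
    gpr = c("HK1 OR HK2", NA, NA, NA)
  ))
  dirs <- tibble::tibble(gene_id = "HK1", predicted = "down_in_M")
  pair <- constrain_metabolic_model(met, dirs)
  expect_equal(
    pair$model_M$reactions$upper_bound[pair$model_M$reactions$id == "HEX"],
    10)
  expect_equal(
    pair$model_E$reactions$upper_bound[pair$model_E$reactions$id == "HEX"],
    1000)
  td <- tidy(pair)
  expect_identical(td$reaction_id[td$ub_E != td$ub_M], "HEX")

  # empty direction set leaves the models identical
  pair0 <- constrain_metabolic_model(
    met, tibble::tibble(gene_id = character(), predicted = character()))
  expect_true(isTRUE(models_equal(pair0$model_E, pair0$model_M)))

  # unknown genes are reported and skipped
  expect_message(
    constrain_metabolic_model(
      met, tibble::tibble(gene_id = "NOPE", predicted = "down_in_M")),
    "skipped")
})

test_that("flux span ratios follow the span definition", {
  fake <- function(mat, ids) {
    structure(list(samples = mat, reaction_ids = ids,
                   kind = rep("internal", length(ids)), seed = 0,
                   thinning = 1, method = "manual"),
              class = "flux_samples")
  }
  sE <- fake(cbind(c(2, 4), c(1, 1)), c("Ra", "Rb"))
  sM <- fake(cbind(c(1, 2), c(1, 1)), c("Ra", "Rb"))
  out <- compare_flux_span(sE, sM)
  # hand-computed: mean spans 3 vs 1.5 -> ratio 0.5; 1 vs 1 -> 1
  expect_equal(out$span_ratio[1], 0.5, tolerance = 1e-5)
  expect_equal(out$span_ratio[2], 1, tolerance = 1e-5)
  expect_identical(out$direction, c("higher_in_E", "similar"))

  idem <- compare_flux_span(sE, sE)
  expect_true(all(idem$span_ratio == 1))
})

test_that("a tightened metabolic subsystem shows lower span in Met_M", {
  withr::with_seed(43, {
    met <- stoich_model(tibble::tibble(
      id = c("UP1", "GLY1", "GLY2", "ALT", "OUT1", "OUT2"),
      equation = c("-> a", "a -> b", "b -> c", "a -> d", "c ->", "d ->"),
      lower_bound = 0, upper_bound = 1000,
      gpr = c(NA, "HK1", "GAPDH", NA, NA, NA)
    ))
    dirs <- tibble::tibble(gene_id = c("HK1", "GAPDH"),
                           predicted = "down_in_M")
    pair <- constrain_metabolic_model(met, dirs)
    sE <- sample_fluxes(pair$model_E, 1500, seed = 1, thinning = 5)
    sM <- sample_fluxes(pair$model_M, 1500, seed = 2, thinning = 5)
    out <- compare_flux_span(sE, sM)
    glyco <- out$reaction_id %in% c("GLY1", "GLY2")
    expect_true(all(out$span_ratio[glyco] < 1))
    expect_true(all(out$direction[glyco] == "higher_in_E"))
  })
})

test_that("predict-then-score on noiseless synthetic truth is perfect", {
  withr::with_seed(47, {
    genes <- sprintf("met%02d", 1:12)
    st <- make_sign_table(genes, pathway_fold = 0.5, seed = 9)
    pred <- predict_metabolic_expression(st$table, pathway_fold = 0.5)
    expect_identical(pred$predicted, st$truth$predicted)
    obs <- tibble::tibble(gene_id = genes, observed = st$truth$predicted)
    g <- glance(score_agreement(pred, obs))
    expect_equal(g$percent_agree, 100)
  })
})
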