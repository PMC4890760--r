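test_that("convert_pathway applies default bounds and rejects bad input", {
  raw <- chain_model()
  raw$reactions$upper_bound <- 5   # arbitrary pre-existing bounds
  m <- convert_pathway(raw)
  expect_true(all(m$reactions$lower_bound == 0))
  expect_true(all(m$reactions$upper_bound == 1000))

  with_ex <- stoich_model(tibble::tibble(id = c("R1", "EX"),
                                         equation = c("A -> B", "-> A")))
  expect_error(convert_pathway(with_ex), "exchange")
})

test_that("modifier rewriting follows the co-substrate scheme", {
  m <- stoich_model(tibble::tibble(id = "R1", equation = "A -> B"))
  m$annotation <- regulatory_annotation(
    modifiers = tibble::tibble(reaction_id = "R1", protein_id = "mod1"))
  out <- insert_modifiers(m)
  # A + mod1 -> B + mod1_p plus the two exchanges
  expect_equal(n_reactions(out), 3)
  expect_equal(out$S["mod1", "R1"], -1)
  expect_equal(out$S["mod1_p", "R1"], 1)
  expect_identical(
    out$species$role[out$species$id == "mod1_p"], "modifier-product")
  ex <- out$reactions[out$reactions$kind == "exchange", ]
  expect_setequal(ex$id, c("EX_mod1_in", "EX_mod1_p_out"))
  expect_equal(out$S["mod1", "EX_mod1_in"], 1)
  expect_equal(out$S["mod1_p", "EX_mod1_p_out"], -1)
})

test_that("a shared modifier adds its species and exchanges only once", {
  m <- stoich_model(tibble::tibble(id = c("R1", "R2"),
                                   equation = c("A -> B", "B -> C")))
  m$annotation <- regulatory_annotation(
    modifiers = tibble::tibble(reaction_id = c("R1", "R2"),
                               protein_id = "m"))
  out <- insert_modifiers(m)
  expect_equal(n_reactions(out), 2 + 2)
  expect_equal(sum(out$species$id == "m_p"), 1)
  # both rewritten columns conserve the modifier: -1 for m, +1 for m_p
  for (rid in c("R1", "R2")) {
    expect_equal(out$S["m", rid], -1)
    expect_equal(out$S["m_p", rid], 1)
  }
})

test_that("a modifier that is already a reactant is ambiguous", {
  m <- stoich_model(tibble::tibble(id = "R1", equation = "A -> B"))
  m$annotation <- regulatory_annotation(
    modifiers = tibble::tibble(reaction_id = "R1", protein_id = "A"))
  expect_error(insert_modifiers(m), "ambiguous")
})

test_that("GPR construction joins complexes, isoforms and inhibitors", {
  m <- stoich_model(tibble::tibble(id = c("R1", "R2", "R3"),
                                   equation = c("A -> B", "B -> C",
                                                "C -> D")))
  ann <- regulatory_annotation(
    modifiers = tibble::tibble(reaction_id = "R1", protein_id = "Pc"),
    inhibitors = tibble::tibble(reaction_id = c("R2", "R1"),
                                protein_id = c("Pi", "Pi")),
    proteins = tibble::tibble(
      protein_id = c("Pc", "Pi"),
      genes = c("gene1 gene2", "gene3 gene4"),
      relation = c("and", "or")
    )
  )
  out <- build_gprs(m, ann)
  g <- function(id) out$reactions$gpr[out$reactions$id == id]
  expect_identical(gpr_deparse(gpr_parse(g("R2"))), "NOT (gene3 OR gene4)")
  # modifier and inhibitor combine as activation AND NOT inhibition
  expect_identical(gpr_deparse(gpr_parse(g("R1"))),
                   "gene1 AND gene2 AND NOT (gene3 OR gene4)")
  expect_true(is.na(g("R3")))
})

test_that("a protein with an empty gene map warns and is skipped", {
  m <- stoich_model(tibble::tibble(id = "R1", equation = "A -> B"))
  ann <- regulatory_annotation(
    modifiers = tibble::tibble(reaction_id = "R1", protein_id = "P0"),
    proteins = tibble::tibble(protein_id = "P0", genes = "", relation = "and")
  )
  expect_warning(out <- build_gprs(m, ann), "no gene mapping")
  expect_true(is.na(out$reactions$gpr[1]))
})

test_that("dead ends are the one-sided rows of S", {
  expect_setequal(find_dead_ends(chain_model()), c("A", "C"))
  closed <- stoich_model(tibble::tibble(
    id = c("R1", "R2", "EX_A", "EX_C"),
    equation = c("A -> B", "B -> C", "-> A", "C ->")
  ))
  expect_length(find_dead_ends(closed), 0)

  withr::with_seed(5, {
    for (i in 1:50) {
      m <- random_pathway(sample(3:10, 1), seed = i)
      # independent row-sign oracle
      expected <- character(0)
      for (s in m$species$id) {
        row <- m$S[s, ]
        nz <- row[row != 0]
        if (all(nz > 0) || all(nz < 0)) expected <- c(expected, s)
      }
      expect_setequal(find_dead_ends(m), expected)
    }
  })
})

test_that("relax_rxns reproduces hand-derived minimal sets", {
  ch <- with_candidate_exchanges(convert_pathway(chain_model()))
  res <- relax_rxns(ch$model, ch$candidates)
  expect_equal(res$objective, 2)
  expect_setequal(res$relaxed, c("EXC_A", "EXC_C"))
  expect_true(all(res$p[res$relaxed] + res$n[res$relaxed] > 0))
  expect_lt(max(abs(ch$model$S %*% res$v)), 1e-6)

  # branch A -> B; B -> C; B -> D needs all three boundary species
  br <- stoich_model(tibble::tibble(
    id = c("R1", "R2", "R3"),
    equation = c("A -> B", "B -> C", "B -> D")))
  bc <- with_candidate_exchanges(convert_pathway(br))
  res_b <- relax_rxns(bc$model, bc$candidates)
  expect_equal(res_b$objective, 3)
  expect_setequal(res_b$relaxed, c("EXC_A", "EXC_C", "EXC_D"))

  # already feasible: pre-opened exchanges
  open <- stoich_model(tibble::tibble(
    id = c("EX_in", "R1", "EX_out"),
    equation = c("-> A", "A -> B", "B ->"),
    lower_bound = 0, upper_bound = 1000))
  oc <- with_candidate_exchanges(open)
  res_o <- relax_rxns(oc$model, oc$candidates)
  expect_equal(res_o$objective, 0)
  expect_length(res_o$relaxed, 0)
})

test_that("relax_rxns matches the exhaustive subset oracle", {
  withr::with_seed(21, {
    for (i in 1:12) {
      m <- convert_pathway(random_pathway(sample(4:8, 1), seed = 100 + i))
      wc <- with_candidate_exchanges(m)
      res <- relax_rxns(wc$model, wc$candidates)
      oracle <- oracle_min_relax(wc$model, wc$candidates)
      expect_equal(res$objective, oracle$k, info = paste("net", i))
      expect_true(
        any(vapply(oracle$sets,
                   function(s) identical(s, sort(res$relaxed)), logical(1))),
        info = paste("net", i, "set", paste(res$relaxed, collapse = ","))
      )
    }
  })
})

test_that("relax_rxns reports structural infeasibility distinctly", {
  # forced internal flux but no candidate can help species B:
  # A -> B with only A's exchange offered
  m <- convert_pathway(stoich_model(tibble::tibble(id = "R1",
                                                   equation = "A -> B")))
  cand <- tibble::tibble(id = "EXC_A", equation = "-> A",
                         lower_bound = 0, upper_bound = 0)
  aug <- fluxtalk:::add_reactions(m, cand)
  expect_error(relax_rxns(aug, "EXC_A"), "no steady state")
})

test_that("add_minimal_exchanges closes all dead ends and is idempotent", {
  m <- convert_pathway(chain_model())
  out <- add_minimal_exchanges(m)
  ex <- out$reactions[out$reactions$kind == "exchange", ]
  expect_equal(nrow(ex), 2)
  expect_setequal(ex$id, c("EX_A_in", "EX_C_out"))
  expect_length(find_dead_ends(out), 0)

  # every internal reaction can carry flux >= 1 simultaneously
  l <- out$reactions$lower_bound
  l[out$reactions$kind == "internal"] <- 1
  expect_true(oracle_feasible(out$S, l, out$reactions$upper_bound))

  again <- add_minimal_exchanges(out)
  expect_true(isTRUE(models_equal(out, again)))

  # a dead-end-free model gains nothing
  pipe <- pipe_model(ub = 1000)
  expect_true(isTRUE(models_equal(pipe, add_minimal_exchanges(pipe))))
})

test_that("add_minimal_exchanges output is dead-end free on random nets", {
  withr::with_seed(31, {
    for (i in 1:8) {
      m <- convert_pathway(random_pathway(sample(4:9, 1), seed = 200 + i))
      out <- add_minimal_exchanges(m)
      expect_length(find_dead_ends(out), 0)
      l <- out$reactions$lower_bound
      l[out$reactions$kind == "internal"] <- 1
      expect_true(oracle_feasible(out$S, l, out$reactions$upper_bound))
      expect_true(isTRUE(models_equal(out, add_minimal_exchanges(out))))
    }
  })
})
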