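# Carving MILP: worked examples, certificate invariants and equivalence
# with the exhaustive oracle.

test_that("TOY6 carve keeps the evidenced route and drops R3", {
  toy <- make_toy6()
  sol <- carve(toy$model, toy$scores)
  expect_setequal(sol$kept, c("EX_A", "T_A", "R1", "R2", "GROWTH"))
  expect_true(check_carve_certificate(toy$model, sol))
  m <- sol$model
  expect_false("D_e" %in% m$mets$id)
  expect_false("g5" %in% model_genes(m))
  expect_equal(nrow(m$rxns), 5)
  # carved model grows on complete medium
  expect_gte(fba(complete_medium(m))$objective, 0.1)
})

test_that("non-negative scores on an unblocked universe keep everything", {
  toy <- make_toy6()
  m <- remove_reactions(toy$model, "EX_D")   # EX_D is structurally blocked
  sc <- reaction_scores(m$rxns$id, rep(0.5, nrow(m$rxns)))
  sol <- carve(m, sc)
  expect_setequal(sol$kept, m$rxns$id)
})

test_that("soft constraints steer the objective as specified", {
  toy <- make_toy6()
  sc <- toy$scores
  sc$score[sc$reaction == "R3"] <- 1
  sc$evidence[sc$reaction == "R3"] <- TRUE
  params <- carve_params(w_soft = 2)
  # R3 now has evidence, but a "should not occur" soft constraint beats it
  sol <- carve(toy$model, sc, params = params, soft = list(R3 = 0))
  expect_false("R3" %in% sol$kept)
  # without the constraint R3 is kept
  sol2 <- carve(toy$model, sc, params = params)
  expect_true("R3" %in% sol2$kept)
  expect_equal(sol$objective,
               oracle_carve(toy$model, carvenet:::score_vector(sc, toy$model),
                            params, soft = list(R3 = 0))$objective,
               tolerance = 1e-6)
})

test_that("hard constraints override bounds and explain infeasibility", {
  toy <- make_toy6()
  # force R3 to carry flux: it must be kept
  sol <- carve(toy$model, toy$scores, hard = list(R3 = c(0.5, 100)))
  expect_true("R3" %in% sol$kept)
  # contradictory hard constraint: blocking the only transporter kills growth
  expect_error(carve(toy$model, toy$scores, hard = list(T_A = c(0, 0))),
               "hard constraints")
  # base infeasibility is reported as such
  dead <- set_bounds(toy$model, "GROWTH", lb = 0, ub = 0.01)
  expect_error(carve(dead, toy$scores), "not solved to optimality")
})

test_that("carve matches the exhaustive oracle on tiny universes", {
  for (seed in c(101, 102, 103)) {
    ru <- tiny_universe(seed)
    sc <- compute_reaction_scores(ru$model,
                                  gene_scores = gene_scores_from_hits(ru$alignment))
    params <- carve_params()
    sol <- carve(ru$model, sc, params = params)
    orc <- oracle_carve(ru$model, carvenet:::score_vector(sc, ru$model), params)
    expect_equal(sol$objective, orc$objective, tolerance = 1e-6,
                 label = paste("seed", seed))
    expect_true(check_carve_certificate(ru$model, sol))
  }
})

test_that("carve is invariant to reaction ordering and reproducible", {
  toy <- make_toy6()
  perm <- c(7, 3, 1, 5, 2, 6, 4)
  shuf <- toy$model
  shuf$rxns <- shuf$rxns[perm, ]
  rownames(shuf$rxns) <- NULL
  sol1 <- carve(toy$model, toy$scores)
  sol2 <- carve(shuf, toy$scores)
  expect_equal(sol1$objective, sol2$objective, tolerance = 1e-9)
  expect_setequal(sol1$kept, sol2$kept)
  sol3 <- carve(toy$model, toy$scores)
  expect_identical(sol1$kept, sol3$kept)
})

test_that("prune_to_model keeps structure for a keep-all solution", {
  toy <- make_toy6()
  m <- remove_reactions(toy$model, "EX_D")
  sc <- reaction_scores(m$rxns$id, rep(1, nrow(m$rxns)))
  sol <- carve(m, sc)
  expect_identical(sol$model$rxns$id, m$rxns$id)
  expect_identical(sol$model$mets$id, m$mets$id)
})
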