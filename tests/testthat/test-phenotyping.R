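# FBA/FVA engines, phenotype arrays, free diffusion, essentiality, metrics.

test_that("fba and fva reproduce hand-computed TOY6 optima", {
  toy <- make_toy6()
  expect_equal(fba(toy$model, med = toy$media$minimal_A)$objective, 10)
  expect_equal(fba(toy$model, med = medium())$objective, 0)
  v <- fva(complete_medium(toy$model), reactions = c("EX_D", "GROWTH"))
  expect_equal(unlist(v[v$reaction == "EX_D", c("min", "max")]),
               c(min = 0, max = 0), tolerance = 1e-9)
  expect_equal(v[v$reaction == "GROWTH", "max"], 100, tolerance = 1e-6)
  # fva with a growth constraint pins the chain fluxes
  v2 <- fva(apply_medium(toy$model, toy$media$minimal_A),
            reactions = "T_A", fraction_of_optimum = 1)
  expect_equal(v2$min, 10, tolerance = 1e-6)
})

test_that("phenotype arrays follow the swap-and-threshold protocol", {
  toy <- make_toy6()
  calls <- simulate_phenotype_array(toy$model, toy$media$minimal_A, "C",
                                    sources = c("A", "D"),
                                    default_source = "A")
  expect_identical(as.logical(calls), c(TRUE, FALSE))
  expect_equal(attr(calls, "growth")[["A"]], 10)
  # growth exactly at the 0.01 threshold counts as viable
  calls2 <- simulate_phenotype_array(toy$model, toy$media$minimal_A, "C",
                                     sources = "A", default_source = "A",
                                     uptake = 0.01)
  expect_true(calls2[["A"]])
  expect_equal(attr(calls2, "growth")[["A"]], 0.01, tolerance = 1e-9)
  # empty array
  expect_length(simulate_phenotype_array(toy$model, toy$media$minimal_A, "C",
                                         sources = character(0),
                                         default_source = "A"), 0)
  # a source without exchange reaction is non-viable, with a warning
  expect_warning(
    calls3 <- simulate_phenotype_array(toy$model, toy$media$minimal_A, "C",
                                       sources = c("A", "ghost"),
                                       default_source = "A"),
    "ghost")
  expect_false(calls3[["ghost"]])
})

test_that("free diffusion bridges transporter gaps only", {
  toy <- make_toy6()
  m <- remove_reactions(toy$model, "T_A")   # A_e now untransported
  expect_equal(fba(m, med = toy$media$minimal_A)$objective, 0)
  m2 <- enable_free_diffusion(m, toy$model)
  expect_equal(fba(m2, med = toy$media$minimal_A)$objective, 10)
  d <- m2$rxns[m2$rxns$id == "DIFF_A", ]
  expect_equal(d$kind, "spontaneous")
  expect_true(carvenet:::gpr_is_empty(d$gpr[[1]]))
  expect_equal(d$lb, -100)
  # a model with complete transporters is unchanged (drop the untransported D)
  complete <- remove_reactions(toy$model, "EX_D")
  m3 <- enable_free_diffusion(complete, toy$model)
  expect_identical(m3$rxns$id, complete$rxns$id)
  # never decreases the viable-call count
  before <- simulate_phenotype_array(m, toy$media$minimal_A, "C",
                                     sources = c("A", "D"),
                                     default_source = "A")
  after <- simulate_phenotype_array(m2, toy$media$minimal_A, "C",
                                    sources = c("A", "D"),
                                    default_source = "A")
  expect_gte(sum(after), sum(before))
})

test_that("gene essentiality follows GPR deletion semantics", {
  toy <- make_toy6()
  med <- toy$media$minimal_A
  no_r3 <- remove_reactions(toy$model, "R3")
  ess <- gene_essentiality(no_r3, med = med)
  expect_true(all(c("g1", "g2") %in% ess))      # sole path genes
  expect_false("g3" %in% ess)                   # isozyme g4 covers R2
  expect_false("g4" %in% ess)
  # with R3 present, deleting g2 reroutes through R3
  ess2 <- gene_essentiality(toy$model, med = med)
  expect_false("g2" %in% ess2)
  expect_true("g1" %in% ess2)
  expect_warning(gene_essentiality(toy$model, med = med,
                                   genes = c("g1", "gX")), "gX")
  # monotone under medium restriction: essentials on the larger medium stay
  # essential on the smaller one
  big <- medium(c(A = 10, D = 10))
  expect_true(all(gene_essentiality(toy$model, med = big) %in%
                    gene_essentiality(toy$model, med = med)))
})

test_that("confusion metrics match the printed formulas", {
  m <- confusion_metrics(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                         c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(m$tp, 2); expect_equal(m$fp, 1)
  expect_equal(m$tn, 3); expect_equal(m$fn, 0)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$f1, 0.8)
  perfect <- confusion_metrics(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_true(all(unlist(perfect[1:5]) == 1))
  none <- confusion_metrics(c(FALSE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(none$precision))
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 1)
  expect_error(confusion_metrics(TRUE, c(TRUE, FALSE)), "same length")
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(4)
  for (k in 1:20) {
    p <- runif(12) < 0.5
    o <- runif(12) < 0.5
    m <- confusion_metrics(p, o)
    if (!is.na(m$precision) && !is.na(m$sensitivity) &&
        (m$precision + m$sensitivity) > 0) {
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                     (m$precision + m$sensitivity), tolerance = 1e-12)
    }
    for (v in unlist(m[1:5])) {
      if (!is.na(v)) expect_true(v >= 0 && v <= 1)
    }
  }
})
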