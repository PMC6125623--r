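# Ensemble generation, Jaccard distances and voting semantics.

test_that("a single-member ensemble equals carve with the realized weights", {
  amb <- make_ambiguous_toy()
  ens <- generate_ensemble(amb$model, amb$scores, n = 1, seed = 11)
  expect_equal(ens$n, 1)
  sol <- ens$members[[1]]
  direct <- carve(amb$model,
                  reaction_scores(amb$model$rxns$id, sol$scores,
                                  evidence = rep(FALSE, nrow(amb$model$rxns))))
  expect_setequal(sol$kept, direct$kept)
  expect_true(check_carve_certificate(amb$model, sol))
})

test_that("both interchangeable routes appear across a 20-member ensemble", {
  amb <- make_ambiguous_toy()
  ens <- generate_ensemble(amb$model, amb$scores, n = 20, seed = 7)
  expect_gte(sum(ens$presence[, "P1"]), 1)
  expect_gte(sum(ens$presence[, "P2"]), 1)
  # exactly one route per member (keeping both costs extra negative weight)
  expect_true(all(rowSums(ens$presence[, c("P1", "P2")]) == 1))
  # every member passes the certificate
  for (sol in ens$members) {
    expect_true(check_carve_certificate(amb$model, sol))
  }
})

test_that("ensembles are bitwise reproducible under a fixed seed", {
  amb <- make_ambiguous_toy()
  e1 <- generate_ensemble(amb$model, amb$scores, n = 6, seed = 42)
  e2 <- generate_ensemble(amb$model, amb$scores, n = 6, seed = 42)
  expect_identical(e1$presence, e2$presence)
  e3 <- generate_ensemble(amb$model, amb$scores, n = 6, seed = 43)
  expect_false(identical(e1$presence, e3$presence))
})

test_that("jaccard distances match set arithmetic", {
  P <- rbind(a = c(R1 = 1, R2 = 1, R3 = 1, R4 = 0),
             b = c(1, 1, 1, 0),
             c = c(0, 1, 1, 1),
             d = c(0, 0, 0, 0))
  d <- jaccard_matrix(P)
  expect_equal(unname(d["a", "b"]), 0)          # identical sets
  expect_equal(unname(d["a", "c"]), 0.5)        # {R1,R2,R3} vs {R2,R3,R4}
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
  # disjoint sets have distance 1
  P2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(jaccard_matrix(P2)[1, 2], 1)
})

test_that("voting is strict at the threshold and monotone in T", {
  calls <- rbind(matrix(TRUE, 6, 1), matrix(FALSE, 4, 1))
  expect_true(vote(calls, 0.5))
  expect_false(vote(rbind(matrix(TRUE, 5, 1), matrix(FALSE, 5, 1)), 0.5))
  expect_false(vote(rbind(matrix(TRUE, 9, 1), matrix(FALSE, 1, 1)), 0.9))
  expect_true(vote(matrix(TRUE, 10, 1), 0.9))
  expect_true(vote(rbind(matrix(TRUE, 2, 1), matrix(FALSE, 8, 1)), 0.1))
  # monotone: raising T never flips negative -> positive
  set.seed(1)
  M <- matrix(runif(200) < 0.5, nrow = 10)
  v_low <- vote(M, 0.1)
  v_mid <- vote(M, 0.5)
  v_high <- vote(M, 0.9)
  expect_true(all(v_mid <= v_low))
  expect_true(all(v_high <= v_mid))
  expect_error(vote(list(c(TRUE), c(TRUE, FALSE))), "equal length")
})

test_that("presence matrices and ensemble SBML round-trip", {
  amb <- make_ambiguous_toy()
  ens <- generate_ensemble(amb$model, amb$scores, n = 4, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_presence_tsv(ens, f)
  expect_identical(read_presence_tsv(f),
                   matrix(ens$presence, nrow = 4,
                          dimnames = dimnames(ens$presence)))
  fx <- withr::local_tempfile(fileext = ".xml")
  write_ensemble_sbml(ens, fx)
  back <- read_ensemble_sbml(fx)
  expect_equal(back$n, 4)
  union_ids <- colnames(ens$presence)[colSums(ens$presence) > 0]
  expect_identical(back$presence[, union_ids, drop = FALSE],
                   matrix(ens$presence[, union_ids, drop = FALSE], nrow = 4,
                          dimnames = list(rownames(ens$presence), union_ids)))
})
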