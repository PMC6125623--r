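# Model container invariants, stoichiometric matrix assembly and media.

test_that("stoichiometric matrix reproduces reaction stoichiometry", {
  mets <- rbind(metabolite("A_c", "c"), metabolite("B_c", "c"))
  rxns <- reaction("R1", c(A_c = -1, B_c = 1), lb = 0)
  m <- new_model("mini", "c", mets, rxns, objective = NA_character_)
  S <- build_stoichiometric_matrix(m)
  expect_equal(as.numeric(S[, "R1"]), c(-1, 1))

  empty <- new_model("empty", "c", NULL, NULL)
  expect_equal(dim(build_stoichiometric_matrix(empty)), c(0L, 0L))

  toy <- make_toy6()
  S6 <- build_stoichiometric_matrix(toy$model)
  expect_equal(Matrix::nnzero(S6), 12)
  # column j reconstructs reaction j exactly
  for (k in seq_len(nrow(toy$model$rxns))) {
    col <- S6[, toy$model$rxns$id[k]]
    st <- toy$model$rxns$stoich[[k]]
    expect_equal(col[names(st)], st[names(st)], ignore_attr = TRUE)
    expect_true(all(col[setdiff(rownames(S6), names(st))] == 0))
  }
})

test_that("model invariants are enforced", {
  mets <- rbind(metabolite("A_c", "c"), metabolite("A_c", "c"))
  expect_error(new_model("bad", "c", mets, reaction("R", c(A_c = -1), lb = 0)),
               "duplicate metabolite")
  expect_error(reaction("R", c(A = -1), lb = 1, ub = 0), "lb > ub")
  expect_error(new_model("bad", "c", metabolite("A_c", "c"),
                         reaction("R", c(B_c = -1), lb = 0)),
               "unknown metabolites")
  # exchange must touch exactly one extracellular metabolite
  mets <- rbind(metabolite("A_e", "e"), metabolite("B_c", "c"))
  expect_error(new_model("bad", c("e", "c"), mets,
                         reaction("EX", c(A_e = -1, B_c = 1), lb = 0,
                                  kind = "exchange")),
               "exactly one metabolite")
  expect_error(new_model("bad", c("e", "c"), mets,
                         reaction("EX", c(B_c = -1), lb = 0, kind = "exchange")),
               "extracellular")
})

test_that("apply_medium follows the uptake sign convention", {
  toy <- make_toy6()
  m <- apply_medium(toy$model, medium(c(A = 10)))
  expect_equal(m$rxns$lb[m$rxns$id == "EX_A"], -10)
  expect_equal(m$rxns$lb[m$rxns$id == "EX_D"], 0)
  # secretion stays open
  expect_equal(m$rxns$ub[m$rxns$id == "EX_A"], 100)

  closed <- apply_medium(toy$model, medium())
  expect_true(all(closed$rxns$lb[closed$rxns$kind == "exchange"] == 0))
  expect_equal(fba(closed)$objective, 0)

  full <- complete_medium(toy$model, 100)
  expect_true(all(full$rxns$lb[full$rxns$kind == "exchange"] == -100))

  expect_warning(apply_medium(toy$model, medium(c(A = 10, nope = 5))),
                 "nope")
  expect_error(medium(c(A = -1)), ">= 0")
})

test_that("media tables round-trip through TSV", {
  tb <- data.frame(medium_id = c("m1", "m1", "m2"),
                   compound_id = c("A", "D", "A"),
                   max_uptake = c(10, 5, 100))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tb, f, sep = "\t", quote = FALSE, row.names = FALSE)
  media <- read_media_tsv(f)
  expect_named(media, c("m1", "m2"))
  expect_equal(unclass(media$m1)[["D"]], 5)
})

test_that("remove/keep reactions prune orphans and drop lost objectives", {
  toy <- make_toy6()
  m <- remove_reactions(toy$model, "EX_D")
  expect_false("D_e" %in% m$mets$id)
  m2 <- keep_reactions(toy$model, c("EX_A", "T_A"))
  expect_true(is.na(m2$objective))
  expect_false("g5" %in% model_genes(remove_reactions(toy$model, "R3")))
})
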