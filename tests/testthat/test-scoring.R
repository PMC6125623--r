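# Alignment parsing, GPR score algebra, normalization and their invariants.

test_that("parse_alignment applies the max-bitscore and e-value rules", {
  hits <- rbind(
    synthetic_hits("g1", 150, queries = "q1"),
    synthetic_hits("g1", 90, queries = "q2"),
    synthetic_hits("g2", 80, queries = "q3", evalues = 1e-3)  # above cutoff
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_tsv(hits, f)
  gs <- parse_alignment(f)
  expect_equal(gs, c(g1 = 150))
  expect_length(parse_alignment(f, evalue_cutoff = 1e-2), 2)

  empty <- withr::local_tempfile(lines = character(0))
  expect_length(parse_alignment(empty), 0)

  bad <- withr::local_tempfile(lines = c(
    paste(c("q", "g", 90, 300, 30, 0, 1, 300, 1, 300, "1e-50", 100),
          collapse = "\t"),
    "q\tg\tbroken"))
  expect_error(parse_alignment(bad), "line 2")
})

test_that("score_reactions applies min-over-complex and sum-over-isozymes", {
  mets <- rbind(metabolite("a_c", "c"), metabolite("b_c", "c"))
  rxns <- rbind(
    reaction("CPLX", c(a_c = -1, b_c = 1), lb = 0, gpr = "g1 and g2"),
    reaction("ISO", c(a_c = -1, b_c = 1), lb = 0, gpr = "g3 or g4"),
    reaction("MIX", c(a_c = -1, b_c = 1), lb = 0, gpr = "(g1 and g2) or g3"),
    reaction("NONE", c(a_c = -1, b_c = 1), lb = 0, gpr = "g9")
  )
  m <- new_model("sc", "c", mets, rxns)
  sc <- score_reactions(m, c(g1 = 4, g2 = 6, g3 = 2, g4 = 3))
  expect_equal(sc$raw[["CPLX"]], 4)      # min rule
  expect_equal(sc$raw[["ISO"]], 5)       # sum rule
  expect_equal(sc$raw[["MIX"]], 6)       # 4 + 2, both complexes present
  expect_false("NONE" %in% names(sc$raw))
  # absent subunit removes the whole complex
  sc2 <- score_reactions(m, c(g1 = 4, g3 = 2))
  expect_equal(sc2$raw[["MIX"]], 2)
  expect_equal(sc2$gprs[["MIX"]]$complexes, list("g3"))
  expect_false("CPLX" %in% names(sc2$raw))
})

test_that("normalization divides by the median and applies defaults", {
  toy <- make_toy6()
  raw <- c(R1 = 2, R2 = 4, T_A = 8)
  tab <- normalize_scores(raw, toy$model)
  s <- setNames(tab$score, tab$reaction)
  expect_equal(unname(s[c("R1", "R2", "T_A")]), c(0.5, 1.0, 2.0))
  expect_equal(unname(s[["R3"]]), -1)       # unscored enzymatic
  expect_equal(unname(s[["EX_A"]]), 0)      # exchange neutral
  expect_equal(unname(s[["GROWTH"]]), 0)    # biomass neutral
  expect_equal(normalize_scores(c(R1 = 7), toy$model)$score[
    normalize_scores(c(R1 = 7), toy$model)$reaction == "R1"], 1)
  expect_error(normalize_scores(numeric(0), toy$model), "nothing to normalize")
  expect_error(normalize_scores(c(R1 = 0), toy$model), "nothing to normalize")
})

test_that("scoring invariants hold on random universes", {
  ru <- make_random_universe(toy_spec(seed = 14, n_distractors = 3,
                                      isozyme_prob = 0.5, complex_prob = 0.3))
  gs <- gene_scores_from_hits(ru$alignment)
  base <- compute_reaction_scores(ru$model, gene_scores = gs)
  # scale equivariance: k * gene scores leaves normalized scores unchanged
  scaled <- compute_reaction_scores(ru$model, gene_scores = gs * 3.7)
  expect_equal(base$score, scaled$score, tolerance = 1e-12)
  # median of evidence-based scores is exactly 1
  expect_equal(median(base$score[base$evidence]), 1)
  # monotonicity: raising one gene score never lowers any raw score
  raw1 <- score_reactions(ru$model, gs)$raw
  gs2 <- gs
  gs2[[1]] <- gs2[[1]] * 5
  raw2 <- score_reactions(ru$model, gs2)$raw
  expect_true(all(raw2[names(raw1)] >= raw1 - 1e-12))
  # organism GPR of a scored reaction evaluates true on the scored genes
  sc <- score_reactions(ru$model, gs)
  for (rid in names(sc$raw)) {
    expect_true(eval_gpr(sc$gprs[[rid]], names(gs)))
  }
})

test_that("reaction score tables round-trip through TSV", {
  toy <- make_toy6()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_scores_tsv(toy$scores, f)
  back <- read_reaction_scores_tsv(f)
  expect_equal(back$reaction, toy$scores$reaction)
  expect_equal(back$score, toy$scores$score)
  expect_equal(back$evidence, toy$scores$evidence)
  expect_setequal(back$gpr[[5]]$complexes, toy$scores$gpr[[5]]$complexes)
})
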