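# Community merging, minimal media and the metabolic interaction potential.

test_that("merging two copies of TOY6 pools the environment", {
  toy <- make_toy6()
  a <- toy$model
  b <- toy$model
  b$id <- "toy6b"
  cm <- merge_community(list(a, b))
  expect_s3_class(cm, "community_model")
  expect_setequal(cm$members, c("toy6", "toy6b"))
  # two cytosolic compartments plus one shared pool
  expect_setequal(cm$compartments, c("c__toy6", "c__toy6b", "pool"))
  # internal reactions duplicated, pool exchanges deduplicated
  expect_equal(sum(cm$rxns$kind == "exchange"), 2)       # A and D
  expect_true(all(c("T_A__toy6", "T_A__toy6b", "EX_A_pool") %in% cm$rxns$id))
  expect_equal(nrow(cm$rxns), 2 * 5 + 2)
  # genes are namespaced: no collisions
  expect_true(all(grepl("__toy6", model_genes(cm))))
  # merged model satisfies steady state (FBA solves)
  expect_equal(fba(apply_medium(cm, medium(c(A = 10))))$status, "optimal")
  expect_error(merge_community(list(a, a)), "distinct")
})

test_that("a single-member merge preserves growth", {
  cf <- make_crossfeed_pair()
  med <- medium(c(A = 10, C = 10))
  cm <- merge_community(list(cf$sp1), med = med)
  expect_equal(fba(cm)$objective,
               fba(cf$sp1, med = med)$objective, tolerance = 1e-9)
  # isolated extracellular with shuttles preserves growth too
  cm2 <- merge_community(list(cf$sp1), isolated_extracellular = TRUE,
                         med = med)
  expect_equal(fba(cm2)$objective, fba(cf$sp1, med = med)$objective,
               tolerance = 1e-9)
})

test_that("community biomass forces every member to grow", {
  cf <- make_crossfeed_pair()
  cm <- merge_community(list(cf$sp1, cf$sp2), community_biomass = TRUE,
                        med = medium(c(A = 10, B = 10, C = 10)))
  expect_equal(cm$objective, "community_growth")
  res <- fba(cm)
  expect_gt(res$objective, 0)
  # both member biomass reactions carry half the community flux each
  expect_equal(unname(res$fluxes[["GROWTH__sp1"]]),
               unname(res$fluxes[["GROWTH__sp2"]]), tolerance = 1e-6)
  expect_equal(unname(res$fluxes[["GROWTH__sp1"]]),
               res$objective / 2, tolerance = 1e-6)
})

test_that("minimal_medium matches exhaustive enumeration", {
  toy <- make_toy6()
  params <- carve_params()
  mm <- minimal_medium(toy$model, params = params)
  expect_equal(mm$compounds, "A")
  expect_equal(mm$size, 1)
  expect_equal(mm$size,
               oracle_minimal_medium(toy$model, c("A", "D"), params))
  # interchangeable carbon sources: size 1, either compound
  m2 <- add_reactions(toy$model,
                      rbind(reaction("EX_B2", c(B2_e = -1), lb = 0, ub = 100,
                                     kind = "exchange"),
                            reaction("T_B2", c(B2_e = -1, C_c = 1), lb = 0,
                                     ub = 100, kind = "transport")),
                      mets = metabolite("B2_e", "e", formula = "CH2O"))
  mm2 <- minimal_medium(m2, params = params)
  expect_equal(mm2$size, 1)
  expect_true(mm2$compounds %in% c("A", "B2"))
  expect_equal(mm2$size, oracle_minimal_medium(m2, c("A", "B2", "D"), params))
  # growth-incapable model errors
  broken <- remove_reactions(toy$model, "T_A")
  expect_error(minimal_medium(broken, params = params), "full candidate pool")
})

test_that("MIP reflects cross-feeding and is zero without it", {
  cf <- make_crossfeed_pair()
  expect_equal(as.integer(mip_score(list(cf$sp1, cf$sp2))), 2)
  expect_equal(as.integer(mip_score(list(cf$sp1))), 0)
  sp1b <- cf$sp1
  sp1b$id <- "sp1b"
  expect_equal(as.integer(mip_score(list(cf$sp1, sp1b))), 0)
  # the interacting pair lives on A alone; alone each needs two compounds
  mip <- mip_score(list(cf$sp1, cf$sp2))
  det <- attr(mip, "details")
  expect_equal(det$interacting$compounds, "A")
  expect_setequal(det$non_interacting$compounds, c("A", "B", "C"))
})

test_that("MIP is non-negative on randomly assembled communities", {
  pool <- community_species_pool()
  for (k in 1:8) {
    members <- with_seed(900 + k, sample(pool, sample(1:3, 1)))
    members <- lapply(seq_along(members), function(i) {
      m <- members[[i]]
      m$id <- paste0(m$id, "_v", i)
      m
    })
    expect_gte(as.integer(mip_score(members)), 0)
  }
})
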