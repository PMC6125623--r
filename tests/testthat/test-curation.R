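# Curation: elemental balance, thermodynamic reversibility, blocked-reaction
# pruning, energy cycles, biomass templates.

test_that("check_mass_balance computes per-element imbalances", {
  mets <- rbind(metabolite("glc_c", "c", formula = "C6H12O6"),
                metabolite("lac_c", "c", formula = "C3H6O3"),
                metabolite("h2o_c", "c", formula = "H2O"),
                metabolite("oh_c", "c", formula = "HO"),
                metabolite("mys_c", "c"))
  rxns <- rbind(
    reaction("FERM", c(glc_c = -1, lac_c = 2), lb = 0),
    reaction("LOSS", c(h2o_c = -1, oh_c = 1), lb = 0),
    reaction("MYST", c(mys_c = -1, lac_c = 1), lb = 0)
  )
  m <- new_model("bal", "c", mets, rxns)
  formulas <- setNames(m$mets$formula, m$mets$id)
  expect_length(check_mass_balance(m$rxns[1, ], formulas), 0)
  expect_equal(check_mass_balance(m$rxns[2, ], formulas), c(H = -1))
  imb <- check_mass_balance(m$rxns[3, ], formulas)
  expect_length(imb, 0)
  expect_true(attr(imb, "unverifiable"))
  # exchange and biomass reactions are exempt
  toy <- make_toy6()
  formulas6 <- setNames(toy$model$mets$formula, toy$model$mets$id)
  ex_row <- toy$model$rxns[toy$model$rxns$id == "EX_A", ]
  expect_length(check_mass_balance(ex_row, formulas6), 0)
  fu <- find_unbalanced(toy$model)
  expect_length(fu$unbalanced, 0)
  ru <- make_random_universe(toy_spec(seed = 5, n_unbalanced = 2))
  expect_setequal(names(find_unbalanced(ru$model)$unbalanced),
                  c("UNB1", "UNB2"))
})

test_that("dG ranges match the closed-form RT ln(1000) span", {
  rt_span <- 8.314e-3 * 298.15 * log(1000)  # both species span 0.01-10 mM
  cases <- list(c(dg0 = -10), c(dg0 = -30), c(dg0 = 20))
  for (cs in cases) {
    rng <- estimate_dg_bounds(c(A_c = -1, B_c = 1), cs[["dg0"]])
    expect_equal(rng, c(cs[["dg0"]] - rt_span, cs[["dg0"]] + rt_span),
                 tolerance = 1e-9)
  }
  # the documented +/-17.12 kJ/mol span for a 0.01-10 mM box
  expect_equal(rt_span, 17.12, tolerance = 1e-3)
  # strict signs where the band does not straddle zero
  expect_true(all(estimate_dg_bounds(c(A_c = -1, B_c = 1), -30) < 0))
  expect_true(all(estimate_dg_bounds(c(A_c = -1, B_c = 1), 20) > 0))
  # stoichiometric exponents and custom concentration bands
  # ln Q = ln[B] - 2 ln[A], [A] fixed at 1e-3 M, [B] in [1e-3, 1] M
  rng2 <- estimate_dg_bounds(c(A_c = -2, B_c = 1), 0,
                             conc = list(A_c = c(1, 1), B_c = c(1, 1000)))
  expect_equal(rng2,
               8.314e-3 * 298.15 * c(log(1e-3) - 2 * log(1e-3),
                                     log(1) - 2 * log(1e-3)),
               tolerance = 1e-9)
  # water and protons are ignored
  rng3 <- estimate_dg_bounds(c(A_c = -1, h2o_c = -1, B_c = 1, h_c = 1), -10)
  expect_equal(rng3, c(-10 - rt_span, -10 + rt_span), tolerance = 1e-9)
  expect_true(all(is.na(estimate_dg_bounds(c(A_c = -1), NA))))
})

test_that("reversibility assignment follows dG > curated > ATP precedence", {
  mets <- rbind(metabolite("a_c", "c"), metabolite("b_c", "c"),
                metabolite("atp_c", "c", compound = "atp"),
                metabolite("adp_c", "c", compound = "adp"))
  rxns <- rbind(
    reaction("NEG", c(a_c = -1, b_c = 1), lb = -100, ub = 100),
    reaction("POS", c(a_c = -1, b_c = 1), lb = -100, ub = 100),
    reaction("ATPUSE", c(atp_c = -1, a_c = -1, adp_c = 1, b_c = 1),
             lb = -100, ub = 100),
    reaction("CURREV", c(a_c = -1, b_c = 1), lb = -100, ub = 100),
    reaction("FREE", c(a_c = -1, b_c = 1), lb = -100, ub = 100)
  )
  m <- new_model("revs", "c", mets, rxns)
  thermo <- data.frame(reaction_id = c("NEG", "POS"),
                       dG0_kJ_mol = c(-30, 30))
  curated <- data.frame(reaction_id = c("CURREV", "NEG"),
                        direction = c("rev_ok", "rev"))
  expect_message(
    m2 <- assign_reversibility(m, thermo, curated = curated),
    "overridden")
  lb <- setNames(m2$rxns$lb, m2$rxns$id)
  ub <- setNames(m2$rxns$ub, m2$rxns$id)
  expect_equal(unname(lb[["NEG"]]), 0)        # strictly negative dG: forward
  expect_equal(unname(ub[["NEG"]]), 100)      # dG beats curated "rev"
  expect_equal(unname(ub[["POS"]]), 0)        # strictly positive dG: backward
  expect_equal(unname(lb[["ATPUSE"]]), 0)     # ATP heuristic
  expect_equal(unname(lb[["CURREV"]]), -100)  # rev_ok leaves bounds alone
  expect_equal(unname(lb[["FREE"]]), -100)    # no evidence at all: untouched
})

test_that("assign_reversibility never widens bounds", {
  ru <- make_random_universe(toy_spec(seed = 9, n_distractors = 3))
  m <- ru$model
  thermo <- data.frame(reaction_id = m$rxns$id,
                       dG0_kJ_mol = rep(c(-30, 30, NA), length.out = nrow(m$rxns)))
  m2 <- assign_reversibility(m, thermo)
  expect_true(all(m2$rxns$lb >= m$rxns$lb))
  expect_true(all(m2$rxns$ub <= m$rxns$ub))
})

test_that("blocked reactions and dead ends are found and pruned to fixpoint", {
  toy <- make_toy6()
  fb <- find_blocked(toy$model)
  expect_equal(fb$blocked, "EX_D")
  expect_equal(fb$dead_ends, "D_e")
  # producer-only metabolite: reaction into it is blocked and it is dead
  ru <- make_random_universe(toy_spec(seed = 21, n_dead_ends = 2))
  fb2 <- find_blocked(ru$model)
  expect_setequal(fb2$blocked, c("DEAD1", "DEAD2"))
  expect_setequal(fb2$dead_ends, c("W1_c", "W2_c"))
  # deleting a mid-pathway step blocks the downstream chain
  cut <- remove_reactions(toy$model, "R2", prune_orphans = FALSE)
  fb3 <- find_blocked(cut)
  expect_true("R1" %in% fb3$blocked)        # B_c has no consumer left
  expect_false("R3" %in% fb3$blocked)       # bypass still feeds growth
  # prune to fixpoint preserves the optimum and finds nothing on re-run
  before <- fba(complete_medium(ru$model))$objective
  pruned <- prune_blocked(ru$model)
  expect_setequal(attr(pruned, "removed")$reactions, c("DEAD1", "DEAD2"))
  after <- fba(complete_medium(pruned))$objective
  expect_equal(before, after, tolerance = 1e-9)
  again <- find_blocked(pruned)
  expect_length(again$blocked, 0)
  expect_length(again$dead_ends, 0)
  # infeasible base model errors
  bad <- set_bounds(toy$model, "GROWTH", lb = 50, ub = 100)
  bad <- set_bounds(bad, "T_A", lb = 0, ub = 1)
  expect_error(find_blocked(bad), "infeasible")
})

test_that("energy-generating cycles are detected and the fix silences them", {
  cyc <- detect_energy_cycles(make_energy_cycle_toy())
  expect_true(cyc$detected)
  expect_setequal(cyc$cycles[[1]], c("R_a", "R_b", "R_c", "ATPM"))
  expect_false(detect_energy_cycles(make_energy_cycle_toy(fixed = TRUE))$detected)
  toy <- make_toy6()
  expect_error(detect_energy_cycles(toy$model), "maintenance")
  # a dG-consistent model has no cycle (fixture with directions fixed)
  ru <- make_random_universe(toy_spec(seed = 2))  # all irreversible forward
  m <- ru$model
  m <- add_reactions(m, reaction("ATPM", setNames(c(-1, 1),
                                                  c(m$mets$id[2], m$mets$id[3])),
                                 lb = 0, ub = 100, kind = "spontaneous"))
  expect_false(detect_energy_cycles(m)$detected)
})

test_that("biomass templates normalise to exactly 1 g/gDW", {
  toy <- make_toy6()
  comp1 <- data.frame(metabolite_id = "C_c", mass_fraction = 1, mw = 100)
  t1 <- build_template(toy$model, comp1, "tmpl1")
  st <- t1$rxns$stoich[[which(t1$rxns$kind == "biomass")]]
  expect_equal(unname(st[["C_c"]]), -10)
  comp2 <- data.frame(metabolite_id = c("B_c", "C_c"),
                      mass_fraction = c(0.5, 0.5), mw = c(100, 200))
  st2 <- build_template(toy$model, comp2)$rxns$stoich[[7]]
  expect_equal(unname(st2[c("B_c", "C_c")]), c(-5, -2.5))
  comp3 <- data.frame(metabolite_id = c("B_c", "C_c"),
                      mass_fraction = c(0.6, 0.4), mw = c(100, 100))
  st3 <- build_template(toy$model, comp3)$rxns$stoich[[7]]
  expect_equal(unname(st3[c("B_c", "C_c")]), c(-6, -4))
  expect_equal(sum(-st3[c("B_c", "C_c")] * 100) / 1000, 1, tolerance = 1e-12)
  expect_error(build_template(toy$model,
                              data.frame(metabolite_id = "nope",
                                         mass_fraction = 1, mw = 10)),
               "nope")
  # the biomass sink product is preserved
  expect_equal(unname(st3[["biomass"]]), 1)
})
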