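# Small pool of single-species fixtures for random community assembly.
# Each species imports the carbon source A, optionally requires one helper
# compound and optionally secretes another, mirroring the cross-feeding
# pair at different compound combinations.

with_seed <- carvenet:::with_seed

community_species <- function(id, needs = NULL, makes = NULL) {
  mets <- rbind(metabolite("A_e", "e", formula = "CH2O"),
                metabolite("A_c", "c", formula = "CH2O"),
                metabolite("X_c", "c", formula = "CH2O", compound = "X"),
                metabolite("biomass", "c", formula = NA, compound = "biomass",
                           boundary = TRUE))
  st <- c(A_c = -1, X_c = 1)
  rxns <- rbind(
    reaction("EX_A", c(A_e = -1), lb = 0, ub = 100, kind = "exchange"),
    reaction("T_A", c(A_e = -1, A_c = 1), lb = 0, ub = 100, kind = "transport"),
    reaction("GROWTH", c(X_c = -1, biomass = 1), lb = 0, ub = 100,
             kind = "biomass")
  )
  for (cpd in unique(c(needs, makes))) {
    mets <- rbind(mets,
                  metabolite(paste0(cpd, "_e"), "e", formula = "X"),
                  metabolite(paste0(cpd, "_c"), "c", formula = "X"))
    rxns <- rbind(rxns,
                  reaction(paste0("EX_", cpd),
                           setNames(-1, paste0(cpd, "_e")), lb = 0, ub = 100,
                           kind = "exchange"),
                  reaction(paste0("T_", cpd),
                           setNames(c(-1, 1), paste0(cpd, c("_e", "_c"))),
                           lb = -100, ub = 100, kind = "transport"))
  }
  if (!is.null(needs)) st[paste0(needs, "_c")] <- -1
  if (!is.null(makes)) st[paste0(makes, "_c")] <- 1
  rxns <- rbind(rxns, reaction("SYN", st, lb = 0, ub = 100))
  new_model(id, c("c", "e"), mets, rxns, objective = "GROWTH")
}

community_species_pool <- function() {
  list(
    community_species("auto"),
    community_species("needC_makeB", needs = "C", makes = "B"),
    community_species("needB_makeC", needs = "B", makes = "C"),
    community_species("needD_makeB", needs = "D", makes = "B"),
    community_species("needB_makeD", needs = "B", makes = "D"),
    community_species("makeC", makes = "C")
  )
}
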