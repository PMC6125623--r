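#' @title Synthetic toy universes and evidence
#' @description Deterministic generators for miniature universal models,
#'   gene-alignment evidence, media and ground-truth organism subnetworks.
#'   They make every stage of the pipeline testable without any database
#'   download: the canonical 6-metabolite linear-pathway universe (`TOY6`),
#'   an ATP-generating futile loop, an ambiguous two-route universe, a
#'   cross-feeding species pair, and seeded random universes with planted
#'   organism subnetworks and matching synthetic alignments.
#' @name fixtures
NULL

#' The canonical TOY6 universe
#'
#' Six metabolites (`A_e`, `A_c`, `B_c`, `C_c`, `D_e` and the `biomass`
#' boundary sink) and seven reactions: exchanges `EX_A`, `EX_D`, transporter
#' `T_A` (gene g1), the two-step route `R1: A_c -> B_c` (g2),
#' `R2: B_c -> C_c` (g3 or g4), the one-step alternative `R3: A_c -> C_c`
#' (g5), and `GROWTH: C_c -> biomass`. All conversions are carbon-balanced
#' by construction (every compound has formula CH2O; D is N). `D_e` is
#' touched only by its exchange, so `EX_D` is structurally blocked — it
#' exercises the blocked-reaction and phenotype-array edge cases.
#'
#' @return list with `model`, `scores` (a `reaction_scores` table with
#'   evidence for the two-step route, default -1 on R3), `gene_scores`,
#'   `media` (named list: `minimal_A` = \{A: 10\}, `complete`), and
#'   `alignment` (synthetic 12-column hit table for genes g1-g4).
#' @export
make_toy6 <- function() {
  mets <- rbind(
    metabolite("A_e", "e", formula = "CH2O"),
    metabolite("A_c", "c", formula = "CH2O"),
    metabolite("B_c", "c", formula = "CH2O"),
    metabolite("C_c", "c", formula = "CH2O"),
    metabolite("D_e", "e", formula = "N"),
    metabolite("biomass", "c", formula = NA, compound = "biomass",
               boundary = TRUE)
  )
  rxns <- rbind(
    reaction("EX_A", c(A_e = -1), lb = 0, ub = 100, kind = "exchange"),
    reaction("EX_D", c(D_e = -1), lb = 0, ub = 100, kind = "exchange"),
    reaction("T_A", c(A_e = -1, A_c = 1), lb = 0, ub = 100, gpr = "g1",
             kind = "transport"),
    reaction("R1", c(A_c = -1, B_c = 1), lb = 0, ub = 100, gpr = "g2"),
    reaction("R2", c(B_c = -1, C_c = 1), lb = 0, ub = 100, gpr = "g3 or g4"),
    reaction("R3", c(A_c = -1, C_c = 1), lb = 0, ub = 100, gpr = "g5"),
    reaction("GROWTH", c(C_c = -1, biomass = 1), lb = 0, ub = 100,
             kind = "biomass")
  )
  model <- new_model("toy6", c("c", "e"), mets, rxns, objective = "GROWTH")
  scores <- reaction_scores(
    reaction = c("EX_A", "EX_D", "T_A", "R1", "R2", "R3", "GROWTH"),
    score = c(0, 0, 1, 1, 1, -1, 0),
    evidence = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    gpr = list(parse_gpr(""), parse_gpr(""), parse_gpr("g1"),
               parse_gpr("g2"), parse_gpr("g3 or g4"), parse_gpr("g5"),
               parse_gpr(""))
  )
  gene_scores <- c(g1 = 100, g2 = 100, g3 = 100, g4 = 100)
  alignment <- synthetic_hits(c("g1", "g2", "g3", "g4"),
                              bitscores = c(100, 100, 100, 100))
  media <- list(minimal_A = medium(c(A = 10)),
                complete = medium(c(A = 100, D = 100)))
  list(model = model, scores = scores, gene_scores = gene_scores,
       media = media, alignment = alignment)
}

# 12-column BLAST-style rows for the given subject genes.
synthetic_hits <- function(genes, bitscores, queries = paste0("q_", genes),
                           evalues = rep(1e-50, length(genes))) {
  data.frame(query = queries, subject = genes, identity = 90.0,
             length = 300L, mismatches = 30L, gaps = 0L, qstart = 1L,
             qend = 300L, sstart = 1L, send = 300L, evalue = evalues,
             bitscore = bitscores, stringsAsFactors = FALSE)
}

#' Write alignment hits as a BLAST outfmt-6 TSV (no header)
#' @param hits a hit data.frame ([synthetic_hits()] layout).
#' @param path output path.
#' @export
write_alignment_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Energy-generating-cycle fixture
#'
#' A three-reaction loop `m1 -> m2 -> m3 -> m1` in which the first step
#' phosphorylates ADP (`R_a: m1 + adp + p -> m2 + atp`, reversible), so one
#' loop turnover regenerates ATP from nothing once all exchanges are closed.
#' The ATP-maintenance drain `ATPM: atp -> adp + p` can then carry unbounded
#' flux. With `fixed = TRUE`, `R_a` is restricted to its thermodynamically
#' favorable (ATP-consuming) direction, which breaks the cycle.
#'
#' @param fixed apply the directionality fix (default `FALSE`).
#' @return a `metabolic_model` with objective `ATPM`.
#' @export
make_energy_cycle_toy <- function(fixed = FALSE) {
  mets <- rbind(
    metabolite("m1_e", "e", formula = "M"),
    metabolite("m1_c", "c", formula = "M"),
    metabolite("m2_c", "c", formula = "M"),
    metabolite("m3_c", "c", formula = "M"),
    metabolite("atp_c", "c", formula = "AP", compound = "atp"),
    metabolite("adp_c", "c", formula = "A", compound = "adp"),
    metabolite("p_c", "c", formula = "P", compound = "p")
  )
  rxns <- rbind(
    reaction("EX_m1", c(m1_e = -1), lb = 0, ub = 100, kind = "exchange"),
    reaction("T_m1", c(m1_e = -1, m1_c = 1), lb = -100, ub = 100,
             kind = "transport"),
    reaction("R_a", c(m1_c = -1, adp_c = -1, p_c = -1, m2_c = 1, atp_c = 1),
             lb = if (fixed) -100 else -100, ub = if (fixed) 0 else 100),
    reaction("R_b", c(m2_c = -1, m3_c = 1), lb = -100, ub = 100),
    reaction("R_c", c(m3_c = -1, m1_c = 1), lb = -100, ub = 100),
    reaction("ATPM", c(atp_c = -1, adp_c = 1, p_c = 1), lb = 0, ub = 100,
             kind = "spontaneous")
  )
  new_model("energy_cycle_toy", c("c", "e"), mets, rxns, objective = "ATPM")
}

#' Ambiguous two-route universe
#'
#' Growth requires converting `A_c` to `C_c`, and two unevidenced,
#' interchangeable single-reaction routes (`P1`, `P2`) can do it. Carving
#' must keep exactly one; which one depends on the randomized weights, so an
#' ensemble explores both.
#'
#' @return list with `model` and `scores`.
#' @export
make_ambiguous_toy <- function() {
  mets <- rbind(
    metabolite("A_e", "e", formula = "CH2O"),
    metabolite("A_c", "c", formula = "CH2O"),
    metabolite("C_c", "c", formula = "CH2O"),
    metabolite("biomass", "c", formula = NA, compound = "biomass",
               boundary = TRUE)
  )
  rxns <- rbind(
    reaction("EX_A", c(A_e = -1), lb = 0, ub = 100, kind = "exchange"),
    reaction("T_A", c(A_e = -1, A_c = 1), lb = 0, ub = 100, gpr = "g1",
             kind = "transport"),
    reaction("P1", c(A_c = -1, C_c = 1), lb = 0, ub = 100),
    reaction("P2", c(A_c = -1, C_c = 1), lb = 0, ub = 100),
    reaction("GROWTH", c(C_c = -1, biomass = 1), lb = 0, ub = 100,
             kind = "biomass")
  )
  model <- new_model("ambiguous_toy", c("c", "e"), mets, rxns,
                     objective = "GROWTH")
  scores <- reaction_scores(
    reaction = c("EX_A", "T_A", "P1", "P2", "GROWTH"),
    score = c(0, 1, -1, -1, 0),
    evidence = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    gpr = list(parse_gpr(""), parse_gpr("g1"), parse_gpr(""), parse_gpr(""),
               parse_gpr(""))
  )
  list(model = model, scores = scores)
}

#' Cross-feeding species pair
#'
#' Two species on a shared extracellular vocabulary \{A, B, C\}: both need
#' the carbon source A; sp1 additionally requires C and secretes B as a
#' byproduct, sp2 requires B and secretes C. Alone, each needs two
#' compounds; together on a shared pool they need only A, so the pair's
#' metabolic interaction potential is 2.
#'
#' @return list of two `metabolic_model`s (`sp1`, `sp2`).
#' @export
make_crossfeed_pair <- function() {
  build_sp <- function(id, needs, makes) {
    mets <- rbind(
      metabolite("A_e", "e", formula = "CH2O"),
      metabolite("A_c", "c", formula = "CH2O"),
      metabolite(paste0(needs, "_e"), "e", formula = "X"),
      metabolite(paste0(needs, "_c"), "c", formula = "X"),
      metabolite(paste0(makes, "_e"), "e", formula = "X"),
      metabolite(paste0(makes, "_c"), "c", formula = "X"),
      metabolite("X_c", "c", formula = "CH2O", compound = "X"),
      metabolite("biomass", "c", formula = NA, compound = "biomass",
                 boundary = TRUE)
    )
    st_syn <- stats::setNames(c(-1, -1, 1, 1),
                              c("A_c", paste0(needs, "_c"), "X_c",
                                paste0(makes, "_c")))
    rxns <- rbind(
      reaction("EX_A", c(A_e = -1), lb = 0, ub = 100, kind = "exchange"),
      reaction(paste0("EX_", needs),
               stats::setNames(-1, paste0(needs, "_e")), lb = 0, ub = 100,
               kind = "exchange"),
      reaction(paste0("EX_", makes),
               stats::setNames(-1, paste0(makes, "_e")), lb = 0, ub = 100,
               kind = "exchange"),
      reaction("T_A", c(A_e = -1, A_c = 1), lb = 0, ub = 100,
               kind = "transport"),
      reaction(paste0("T_", needs),
               stats::setNames(c(-1, 1), paste0(needs, c("_e", "_c"))),
               lb = -100, ub = 100, kind = "transport"),
      reaction(paste0("T_", makes),
               stats::setNames(c(-1, 1), paste0(makes, c("_c", "_e"))),
               lb = -100, ub = 100, kind = "transport"),
      reaction("SYN", st_syn, lb = 0, ub = 100),
      reaction("GROWTH", c(X_c = -1, biomass = 1), lb = 0, ub = 100,
               kind = "biomass")
    )
    new_model(id, c("c", "e"), mets, rxns, objective = "GROWTH")
  }
  # note: the synthesis step consumes the required cofactor catalytically is
  # simplified to stoichiometric consumption; it keeps the LP tiny.
  sp1 <- build_sp("sp1", needs = "C", makes = "B")
  sp2 <- build_sp("sp2", needs = "B", makes = "C")
  list(sp1 = sp1, sp2 = sp2)
}

#' Specification of a random toy universe
#'
#' @param n_pathways number of independent linear pathways feeding biomass.
#' @param pathway_len reactions per pathway after the transporter.
#' @param isozyme_prob probability a pathway step carries two isozymes.
#' @param complex_prob probability a pathway step is catalysed by a
#'   two-subunit complex.
#' @param n_dead_ends planted producer-only dead-end reactions.
#' @param n_unbalanced planted atomically unbalanced reactions.
#' @param n_distractors unevidenced distractor reactions between pathway
#'   intermediates.
#' @param energy_cycle embed an ATP-regenerating futile loop.
#' @param seed integer seed; generators are pure functions of it.
#' @return a list of class `toy_spec`.
#' @export
toy_spec <- function(n_pathways = 3, pathway_len = 3, isozyme_prob = 0.3,
                     complex_prob = 0.2, n_dead_ends = 0, n_unbalanced = 0,
                     n_distractors = 0, energy_cycle = FALSE, seed = 42L) {
  stopifnot(n_pathways >= 1, pathway_len >= 1)
  structure(list(n_pathways = n_pathways, pathway_len = pathway_len,
                 isozyme_prob = isozyme_prob, complex_prob = complex_prob,
                 n_dead_ends = n_dead_ends, n_unbalanced = n_unbalanced,
                 n_distractors = n_distractors, energy_cycle = energy_cycle,
                 seed = as.integer(seed)), class = "toy_spec")
}

#' Generate a random toy universe with a planted organism subnetwork
#'
#' Builds `n_pathways` independent linear pathways (exchange, transporter
#' with a gene, `pathway_len` conversion steps with genes, a biomass
#' reaction draining every pathway end product) — the planted organism —
#' plus optional unevidenced distractor reactions, dead ends, unbalanced
#' reactions and an energy cycle. A synthetic alignment gives every planted
#' gene log-normal bitscores (median about 100); distractor genes get no
#' hits. The same seed reproduces the universe bit for bit.
#'
#' @param spec a [toy_spec()].
#' @return list with `model`, `planted` (ground-truth reaction ids),
#'   `alignment` (12-column hit table) and `genes` (planted gene ids).
#' @export
make_random_universe <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  with_seed(spec$seed, {
    mets <- list()
    rxns <- list()
    genes <- character(0)
    planted <- character(0)
    ends <- character(0)
    cyto <- character(0)
    for (p in seq_len(spec$n_pathways)) {
      s_e <- sprintf("S%d_e", p)
      mets[[length(mets) + 1L]] <- metabolite(s_e, "e", formula = "CH2O")
      chain <- c(sprintf("S%d_c", p),
                 sprintf("M%d_%d_c", p, seq_len(spec$pathway_len)))
      for (cm in chain) {
        mets[[length(mets) + 1L]] <- metabolite(cm, "c", formula = "CH2O")
      }
      cyto <- c(cyto, chain)
      ex_id <- sprintf("EX_S%d", p)
      rxns[[length(rxns) + 1L]] <- reaction(ex_id, stats::setNames(-1, s_e),
                                            lb = 0, ub = 100,
                                            kind = "exchange")
      tg <- sprintf("gT%d", p)
      genes <- c(genes, tg)
      t_id <- sprintf("T%d", p)
      rxns[[length(rxns) + 1L]] <- reaction(
        t_id, stats::setNames(c(-1, 1), c(s_e, chain[1])), lb = 0, ub = 100,
        gpr = tg, kind = "transport")
      planted <- c(planted, ex_id, t_id)
      for (j in seq_len(spec$pathway_len)) {
        g <- sprintf("g%d_%d", p, j)
        u <- stats::runif(1)
        rule <- if (u < spec$complex_prob) {
          genes <- c(genes, g, paste0(g, "b"))
          paste0(g, " and ", g, "b")
        } else if (u < spec$complex_prob + spec$isozyme_prob) {
          genes <- c(genes, g, paste0(g, "b"))
          paste0(g, " or ", g, "b")
        } else {
          genes <- c(genes, g)
          g
        }
        r_id <- sprintf("R%d_%d", p, j)
        rxns[[length(rxns) + 1L]] <- reaction(
          r_id, stats::setNames(c(-1, 1), c(chain[j], chain[j + 1])),
          lb = 0, ub = 100, gpr = rule)
        planted <- c(planted, r_id)
      }
      ends <- c(ends, chain[length(chain)])
    }
    mets[[length(mets) + 1L]] <- metabolite("biomass", "c", formula = NA,
                                            compound = "biomass",
                                            boundary = TRUE)
    rxns[[length(rxns) + 1L]] <- reaction(
      "GROWTH", stats::setNames(c(rep(-1, length(ends)), 1),
                                c(ends, "biomass")),
      lb = 0, ub = 100, kind = "biomass")
    planted <- c(planted, "GROWTH")
    if (spec$n_distractors > 0) {
      for (d in seq_len(spec$n_distractors)) {
        pick <- sample(cyto, 2)
        rxns[[length(rxns) + 1L]] <- reaction(
          sprintf("DIS%d", d), stats::setNames(c(-1, 1), pick),
          lb = 0, ub = 100, gpr = sprintf("gDIS%d", d))
      }
    }
    if (spec$n_dead_ends > 0) {
      for (d in seq_len(spec$n_dead_ends)) {
        w <- sprintf("W%d_c", d)
        mets[[length(mets) + 1L]] <- metabolite(w, "c", formula = "CH2O")
        rxns[[length(rxns) + 1L]] <- reaction(
          sprintf("DEAD%d", d), stats::setNames(c(-1, 1), c(sample(cyto, 1), w)),
          lb = 0, ub = 100)
      }
    }
    if (spec$n_unbalanced > 0) {
      for (d in seq_len(spec$n_unbalanced)) {
        pick <- sample(cyto, 2)
        rxns[[length(rxns) + 1L]] <- reaction(
          sprintf("UNB%d", d), stats::setNames(c(-1, 2), pick),
          lb = 0, ub = 100)
      }
    }
    if (spec$energy_cycle) {
      cyc <- make_energy_cycle_toy()
      keep <- !(cyc$mets$id %in% c("m1_e", "m1_c"))
      mets[[length(mets) + 1L]] <-
        cyc$mets[cyc$mets$id %in% c("m2_c", "m3_c", "atp_c", "adp_c", "p_c"), ]
      first <- cyto[1]
      cyc_rxns <- cyc$rxns[cyc$rxns$id %in% c("R_a", "R_b", "R_c", "ATPM"), ,
                           drop = FALSE]
      for (k in seq_len(nrow(cyc_rxns))) {
        st <- cyc_rxns$stoich[[k]]
        names(st)[names(st) == "m1_c"] <- first
        cyc_rxns$stoich[[k]] <- st
      }
      rxns[[length(rxns) + 1L]] <- cyc_rxns
    }
    model <- new_model(sprintf("random_universe_%d", spec$seed), c("c", "e"),
                       do.call(rbind, mets), do.call(rbind, rxns),
                       objective = "GROWTH")
    bits <- stats::rlnorm(length(genes), meanlog = log(100), sdlog = 0.4)
    alignment <- synthetic_hits(genes, bitscores = round(bits, 1))
    list(model = model, planted = planted, alignment = alignment,
         genes = genes)
  })
}
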