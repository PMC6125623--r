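# carvenet

Top-down reconstruction of genome-scale metabolic models in R.

## The problem

Constraint-based (stoichiometric) models let you predict growth, substrate
utilisation, gene essentiality and cross-feeding from a genome. Building one
the traditional way — assemble a draft from annotation, then hand-curate mass
balance, reaction directionality, futile cycles and gaps — takes weeks per
organism. `carvenet` implements the *top-down* alternative: start from a
single curated, simulation-ready **universal model** of metabolism and
*carve* an organism-specific model out of it, keeping the curation effort and
discarding everything the organism's genome gives no evidence for. The same
machinery merges single-species models into microbial community models.

The package is aimed at microbial systems biologists who want reproducible,
scriptable reconstruction: every pipeline stage is an ordinary R function
over an ordinary data structure, and every optimisation is checkable against
a brute-force oracle on toy inputs.

## The method

1. **Curation** (`check_mass_balance`, `assign_reversibility`,
   `prune_blocked`, `detect_energy_cycles`, `build_template`): screen a draft
   universe for atomically unbalanced reactions; set reaction bounds
   irreversible whenever the Gibbs-energy range
   `dG_r = dG0_r + RT ln Q` (Q extremised over metabolite concentrations,
   default 0.01–10 mM) is strictly signed; remove blocked reactions and
   dead-end metabolites found by flux variability analysis; flag
   ATP-generating cycles; normalise biomass compositions to 1 g/gDW.
2. **Scoring** (`compute_reaction_scores`): BLAST-style hits against the
   universe's gene database become gene scores (best bitscore); a protein
   complex scores the *minimum* over its subunits, a reaction *sums* its
   isozymes; scores are normalised to median 1; enzymatic reactions without
   evidence score −1, spontaneous/exchange reactions 0.
3. **Carving** (`carve`): the MILP

   ```
   max  s' (y_f + y_r)
   s.t. S v = 0
        −M y_r + ε y_f ≤ v ≤ −ε y_r + M y_f
        y_f + y_r ≤ 1,  y binary
        v_growth ≥ v_min
   ```

   with ε = 0.001, M = 100 mmol/gDW/h and v_min = 0.1 h⁻¹ selects a
   connected, growth-capable subnetwork maximising total evidence; every
   active reaction must carry ≥ ε flux in one simultaneous flux
   distribution, so pathways are gapless by construction. Soft constraints
   (±1/0 direction preferences) reweight the objective; hard constraints
   override flux bounds.
4. **Gap-filling** (`gapfill`): if the carved model misses growth on a
   stated medium, add universe reactions minimising `Σ 1/(1+s_i) y_i` — a
   score-weighted parsimony.
5. **Ensembles** (`generate_ensemble`, `vote`): re-draw the weights of
   unevidenced reactions from U[−1, 0) and re-solve to expose alternative
   network structures; phenotypes are called by voting with a strict
   threshold.
6. **Communities** (`merge_community`, `minimal_medium`, `mip_score`):
   namespace each member into its own compartments, share one extracellular
   pool, optionally couple growth through a community biomass; the metabolic
   interaction potential (MIP) is the reduction in minimal-medium size when
   members may exchange metabolites.

Models are read/written as SBML L3+FBC2, legacy COBRA-dialect SBML, or a
documented native JSON dialect. LP/MILPs are solved through a pluggable
backend; the default shells out to SciPy's HiGHS (no R solver dependency).

## Worked example

```r
library(carvenet)

toy <- make_toy6()          # 6-metabolite universe, scores, media, alignment
sol <- carve(toy$model, toy$scores)
sort(sol$kept)
#> [1] "EX_A"   "GROWTH" "R1"     "R2"     "T_A"
```

The universe offers two routes from the carbon source A to the biomass
precursor C: the evidenced two-step route R1+R2 (genes g2, g3/g4) and the
unevidenced bypass R3 (score −1). Carving keeps the evidenced route, the
transporter and the exchange, and drops R3 and the structurally blocked
exchange EX_D. The carved model still grows at the input rate:

```r
fba(sol$model, med = toy$media$minimal_A)$objective
#> [1] 10
```

and single-gene deletions behave as the GPRs dictate (g3 has isozyme g4, so
only the transporter gene is essential once the bypass exists):

```r
gene_essentiality(toy$model, med = toy$media$minimal_A)
#> [1] "g1"
```

Community example — two species that each need the carbon source plus one
compound the other secretes:

```r
cf <- make_crossfeed_pair()
mip_score(list(cf$sp1, cf$sp2))
#> [1] 2
```

Alone each species needs two compounds; sharing a pool they live on the
carbon source only, so the pair can exchange 2 compounds (MIP = 2).

Command line (thin wrappers over the same functions):

```sh
Rscript inst/cli/carve.R --universe universe.xml --alignment hits.tsv \
        --output model.xml --media M9 --media-file media.tsv
Rscript inst/cli/merge.R sp1.xml sp2.xml --community-biomass --mip --json
```

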