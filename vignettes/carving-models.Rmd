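---
title: "Top-down metabolic reconstruction: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Top-down metabolic reconstruction: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(carvenet)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic fixtures do and do not
emulate, and the choices we made where the method left the design open.

## The top-down reconstruction model

A constraint-based metabolic model is a stoichiometric matrix $S$
(metabolites × reactions), flux bounds $lb \le v \le ub$ (mmol/gDW/h), and a
biomass pseudo-reaction whose flux is the growth rate (h⁻¹). Flux balance
analysis (FBA) assumes steady state, $S v = 0$, and maximises biomass flux
by LP. Metabolites flagged as *boundary* species (the biomass sink in our
fixtures) appear in the structural matrix but are exempt from the
steady-state rows — the standard SBML `boundaryCondition` semantics.

Top-down reconstruction inverts the usual draft-then-curate workflow: all
curation is invested once into a **universal model**, and each organism
model is obtained by *removing* what the genome does not support, so the
curated properties (balanced reactions, consistent directions, no futile
cycles, gapless routes to biomass) are inherited rather than re-earned.

### Reaction scoring

Alignment evidence enters as a 12-column BLAST-style table. Per database
gene we keep the **best bitscore** among hits with e-value ≤ 10⁻⁶. The
method's description does not fix the score type or a hit cutoff; we chose
bitscore because it is alignment-length-normalised and database-size
independent, and 10⁻⁶ as a conventional homology cutoff (both overridable).
GPR algebra then maps genes to reactions: a complex (AND) scores the
minimum over its subunits and is *absent* if any subunit is unscored —
presence of a complex requires all subunits, and a minimum over a missing
value would be undefined; isozymes (OR) sum. Scores are normalised to
median 1, unevidenced enzyme-catalysed reactions get −1, spontaneous and
exchange reactions 0 (always allowed, never rewarded). One caveat on
"median exactly 1": with an even number of scored reactions the median is
an average of two rescaled values, so it is exact only to a rounding unit;
the acceptance check allows 10⁻¹² for this reason.

### The carving MILP

$$\max s^\top (y^f + y^r) \quad \text{s.t.} \quad S v = 0,\;
-M y^r + \varepsilon y^f \le v \le -\varepsilon y^r + M y^f,\;
y^f + y^r \le 1,\; v_{growth} \ge v_{min}$$

* $\varepsilon$ = 0.001 mmol/gDW/h — the minimum flux an *active* reaction
  must carry. It is what makes selected pathways gapless: all kept
  reactions must be simultaneously active in one certificate flux vector.
* $M$ = 100 mmol/gDW/h — the flux cap; also the uptake rate used for the
  "complete medium" (all exchanges open) under which carving runs, making
  reconstruction context independent.
* $v_{min}$ = 0.1 h⁻¹ — minimum growth of the carved model.

The displayed inequalities are strict in the method's statement; MILP
solvers need closed constraints, so we use ≥/≤ — $\varepsilon$ already
provides the separation. Certificates are validated with a 10⁻⁶ slack
(solver integrality/feasibility noise); this slack is a numerical
tolerance, not a loosening of $\varepsilon$.

Soft constraints (+1 forward preferred / −1 backward preferred / 0 should
not occur) add a weight to the corresponding direction binary; the weight
magnitude is not quantified in the method, we use $w_{soft} = 1$ on the
normalized-score scale, i.e. one soft constraint outweighs one
median-evidence reaction. Hard constraints replace flux bounds outright and
may make the MILP infeasible; `carve()` distinguishes that case by
re-solving without them.

Exchange reactions participate with binaries and score 0 (an open
question in the method's statement): they cost nothing, so media remain
usable downstream, but they are still dropped when structurally blocked.

### Gap-filling

Per medium, in user order, the MILP minimises $\sum_{i \in R}
\frac{1}{1+s_i} y_i$ over universe reactions absent from the model, subject
to growth ≥ $v_{min}$; additions accumulate across media. $s_i$ is the
normalized evidence score clamped to ≥ 0, with 0 for unscored reactions —
the −1 default never enters the weights (it would make $1/(1+s)$ blow up);
with all $s_i$ equal the objective degenerates to counting added reactions
(parsimony). Sequential processing makes the result order-dependent; this
is a property of the method itself and is mitigated by ensembles. Candidate
direction is governed by a single binary gating the universe bounds, as in
the method's displayed program (not the two-binary scheme of carving).

### Ensembles and voting

Alternative optima are explored by re-drawing the weights of unevidenced
reactions; the randomisation law is unspecified in the method, we use
U[−1, 0): penalties stay penalties, bounded by the default −1, and the
evidence scores are never jittered. A consensus phenotype is positive iff
the fraction of agreeing members is *strictly greater* than the threshold
$T$ ∈ {0.1, 0.5, 0.9}. Ensembles are reproducible bit for bit from the
seed; members are solved in one backend batch.

### Communities and the MIP score

Members are namespaced (`met__species`, genes too) and share an
extracellular pool; optionally each keeps an isolated extracellular
compartment bridged to the pool by reversible shuttles. The community
biomass, when requested, drains each member's biomass with equal weight
$1/n$ — member abundances are not part of the method's statement, equal
weights are the neutral choice — and forces all members to grow together.

The metabolic interaction potential is implemented as
$\mathrm{MIP} = |\mathcal{M}_{non}| - |\mathcal{M}_{int}|$: the minimal
medium of the non-interacting community minus that of the interacting one.
The exact formulation lives in the literature the method cites; our
reading: *non-interacting* = same members with the pool shuttles removed
and private per-member exchanges, with one binary per base compound gating
every member's exchange of that compound (the environment supplies a
compound to everyone or to no one). Minimal media are computed by MILP
(minimise enabled compounds s.t. community growth ≥ 0.1 h⁻¹); ties among
equally small media are broken by solver determinism — only the size
enters MIP, which is therefore well defined and provably ≥ 0.

### Thermodynamic reversibility

$\Delta G_r$ ranges come from $\Delta G^0_r + RT \ln Q$ with $T$ = 298.15 K
and $Q$ extremised over concentration boxes (default 0.01–10 mM, measured
metabolites overridable via a table; water and protons excluded, as
transformed energies already account for them). Strictly negative range ⇒
forward only; strictly positive ⇒ backward only. For reactions without
$\Delta G^0$: first a curated-direction table, then the heuristic that
ATP-consuming reactions do not run backwards. The method lists these rules
without ordering them; we fixed the precedence ΔG > curated > ATP because
measured thermodynamics should overrule curation conventions, and the ATP
rule is the weakest signal. Conflicts are logged, ΔG wins.

Blocked-reaction analysis runs FVA on the complete medium with *no* growth
constraint: curation asks which reactions can ever carry flux, not which
support a phenotype. A dead-end metabolite is one all of whose reactions
are blocked (it can never be both produced and consumed at steady state).
Energy-generating cycles are detected by closing every exchange and
maximising the ATP-maintenance flux; anything above 10⁻⁶ mmol/gDW/h
(above LP solver noise) is a cycle, and the support of the optimal flux
names the offending loop.

### Biomass templates

Given mass fractions $f_i$ (g/gDW) and molecular weights $MW_i$ (g/mol),
the molar coefficients are $c_i = 1000 f_i / MW_i$ mmol/gDW after
renormalising $\sum f_i = 1$, so $\sum c_i MW_i / 1000 = 1$ exactly: unit
biomass flux drains one gram dry weight per hour, which is what makes the
biomass flux interpretable as a growth rate.

## The solver backend

No LP/MILP solver is available in this R environment, and solver internals
are explicitly out of scope for the method; we therefore define a small
backend contract (sparse constraint triplets, row/variable bounds,
integrality, batch solving) and default to HiGHS via the SciPy found on the
PATH, exchanging problems as JSON files. Batching matters: interpreter
startup (~0.4 s) dwarfs the solve time of these problems, so FVA, gene
deletions, phenotype arrays, ensembles and the test oracles all submit one
batch per analysis. MILPs are solved to a zero relative gap so that
optimality comparisons against enumeration oracles are exact.

## What the synthetic fixtures establish — and what they don't

The generators plant a known ground truth: linear pathways with genes and
log-normal bitscores (median ≈ 100, mirroring the empirical shape of
alignment-score distributions), plus deliberate defects — unevidenced
distractor reactions, producer-only dead ends, atomically unbalanced
reactions, a three-reaction ATP-regenerating loop. A green planted-recovery
test establishes that carving returns exactly the evidenced, growth-capable
subnetwork when evidence and truth coincide and distractors are unneeded.
It does *not* establish performance on real genomes: real universes have
thousands of reactions with promiscuous connectivity, evidence is noisy and
incomplete, and alternative optima abound. Real-data claims (benchmark
accuracies, ensemble variability magnitudes, community-size effects) are
out of reach at desk scale, which is why the acceptance report contains no
numeric headline targets and the checks are property-based instead.

The canonical TOY6 fixture deserves one note: its array compound D is
connected only through its exchange reaction, which is therefore
structurally blocked. This is intentional (it exercises the
blocked-reaction detector and the non-viable phenotype call), and it means
TOY6 is *not* an example of a fully unblocked universe.

## Numerical choices

* LP/MILP feasibility and certificate slack: 10⁻⁶; blocked-reaction flux
  tolerance: 10⁻⁹; biomass normalisation: exact to 10⁻⁹.
* Phenotype viability: growth ≥ 0.01 h⁻¹, read as *at least* (inclusive),
  with a 10⁻⁹ slack for solver noise at the boundary.
* Gene essentiality cutoff: growth < 10⁻⁶ h⁻¹ — deliberately distinct from
  the 0.01 viability threshold (which is part of the phenotype-array
  protocol); essentiality asks whether growth is possible at all.
* Tie-breaking among alternate carve optima: deterministic solver with a
  fixed variable order; alternatives are explored *deliberately* via
  ensembles rather than left to solver whim.
* Undefined performance ratios (zero denominators) are reported as `NA`,
  never as 0 — averaging a fake 0 into a benchmark would bias it.

## Known limitations

* The default solver backend requires a Python/SciPy installation; there is
  no in-process fallback.
* Gap-filling is sequential per medium: the media order can change the
  result (inherent to the approach; use ensembles to gauge it).
* `apply_medium` leaves secretion bounds untouched at their universe values
  (the method does not state how they are set; we keep them at $M$).
* Community merging assumes members share an extracellular compound
  vocabulary; no identifier translation is attempted.
* SBML support covers the FBC2/COBRA subset this package emits (plus
  cobrapy-style files of the same shape); it is not a general SBML parser.
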