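---
title: "Designing multi-enzyme synthesis pathways with pathcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-enzyme synthesis pathways with pathcascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcascade)
```

## The problem

In vitro enzyme cascades, cell hydrolysates and permeabilized cells make it
possible to run multi-step syntheses outside a living cell. Designing such a
route by hand is hard: reaction databases contain thousands of candidate
enzymes, many substrate-product relationships are only meaningful in one
direction, and a chain of individually plausible reactions may be
thermodynamically hopeless or depend on intermediates nothing supplies.
`pathcascade` automates the three stages of that design problem:

1. **Network reconstruction** — build a directed network of *arcs*
   (biologically meaningful substrate-to-product edges within single
   reactions) from KEGG-style reaction records, curated reaction-pair tables
   and a table of transformed reaction Gibbs energies.
2. **Path finding** — enumerate candidate pathways to a target metabolite
   with a mixed-integer linear program (MILP) that couples graph topology
   with reaction stoichiometry. The start metabolite is *not* fixed in
   advance: the search discovers suitable starting points itself.
3. **Filtering, ranking and reporting** — discard candidates that cannot be
   bootstrapped from freely available metabolites, order the rest by seven
   biochemical criteria, and emit per-candidate thermodynamic profiles,
   reactant balances, side-reaction lists and SBML files.

Because the reaction mixture shares a single compartment, no steady-state
assumption is made: externally supplied ("pool") metabolites may be consumed
freely, everything else must be net-produced.

## Network model

Reactions are parsed from a KEGG-flat-file subset (ENTRY / EQUATION /
COMMENT) or an equivalent TSV. Three curated exclusion rules apply, each
with a fixed reason code: records flagged *generic* or *incomplete* in their
comments (`comment`), records with symbolic stoichiometric coefficients such
as *n* (`symbolic`), and records involving glycans, i.e. G-number compounds
(`glycan`). When several rules fire, the reason precedence is comment >
symbolic > glycan — an arbitrary but fixed order chosen for deterministic
logs.

**Reversibility.** Directionality comes from the transformed reaction Gibbs
energy at 1 mM reactant concentration, pH 7 and 25 °C. With the default
threshold of 15 kJ/mol:

* |ΔrG′m| < 15 — the reaction is *reversible* and is split into a
  forward/backward pair of directed reactions with negated stoichiometry and
  negated energy;
* ΔrG′m ≤ −15 — irreversible as written;
* ΔrG′m ≥ +15 — irreversible in the *reverse* direction: the equation is
  flipped and the energy negated. The data source does not dictate whether
  such reactions should be flipped or dropped; we flip, because the reverse
  reaction is exactly as well evidenced as the forward one, and flag the
  directed copy (`direction = "backward"`).
* no energy available — irreversible in the direction written
  (conservative: nothing licenses running it backwards).

**Arcs.** Only *main* and *trans* reaction pairs become arcs by default;
cofac-, ligase- and leave-pairs can be admitted explicitly. Arcs touching
cofactors, excluded or generic metabolites are dropped to prevent
meaningless shortcuts (every phosphorylation would otherwise connect through
ATP). One arc is kept per (substrate, product, reaction) triple.

**Metabolite categories.** *Start* metabolites are arc members with
molecular mass in the half-open window (0, 300] — the upper bound included,
mass exactly 0 excluded, and metabolites without mass data conservatively
excluded — plus the curated *basis* list (cheap hub metabolites such as
glucose; the curator may add heavier compounds like sucrose). The
*metabolite pool* is start ∪ basis ∪ cofactors ∪ excluded: everything
treated as freely available. All remaining metabolites are *external* and
must be produced, never taken up.

## The path-finding MILP

Binary variables `u[i -> j]` select arcs of a *linear path*; continuous
fluxes `v_r` and binary activity indicators `z_r` certify that the path is
stoichiometrically executable. The constraints are:

* exactly one arc enters the target and none leaves it;
* a start metabolite may begin a path (out-degree may exceed in-degree);
  a basis metabolite may *only* begin a path (no arc may enter it);
  every non-start node balances in- and out-degree; no node is entered
  twice — together these force a simple connected chain from some start
  metabolite to the target;
* non-pool metabolites have non-negative net production and the target at
  least one unit; active fluxes are scaled into [1, Max] via
  `z_r ≤ v_r ≤ Max·z_r`; a reaction and its reverse are never active
  together; and every chosen arc must be *realised* by at least one active
  reaction containing it.

The objective minimises the arc count plus the active-reaction count
weighted by 1/(|R|+1). Since the second term is always below 1, path length
strictly dominates: the first solution's arc count is the minimum feasible
path length, and supplying reactions are minimised only as a tie-break.

Active reactions that realise path arcs form the set Z′; the remaining
active reactions are *supplying reactions* producing non-pool substrates
consumed along the way. A candidate is the pair (metabolite path, Z′) —
the same path with different realising reactions is a genuinely different
enzyme choice and is enumerated separately.

**Solution exclusion.** After each solution, cuts are added so the solver
streams distinct candidates in nondecreasing objective order: per new
metabolite path a binary marker with three constraints ties the marker to
"exactly this arc set" while still admitting a path that strictly extends a
previous one through its start node; and per returned solution one cut
forbids reactivating that path's exact Z′ (hence also any superset of it on
the same path). Enumeration ends when the model becomes infeasible.

## Solving the MILP

No mixed-integer programming solver is available as an R package dependency
here, and the models involved are small (tens of binaries), so the package
ships an exact solver of its own: a dense two-phase primal simplex with row
equilibration, a minimum pivot magnitude of 1e-7 (pivoting on
near-tolerance elements destroys conditioning), largest-pivot tie-breaking,
and a switch to Bland's least-index anti-cycling rule after 3(m+n)
iterations; around it, depth-first branch-and-bound on the most fractional
binary, exploring the rounded branch first. Binaries are read at an integer
tolerance of 1e-6; objective comparisons use 1e-7. The solver is
deterministic, which gives reproducible candidate streams and byte-identical
pipeline reruns. It is validated in the test suite against hand-solved
programs and exhaustive enumeration over binary assignments.

After each MILP solve a secondary LP re-minimises total flux with all
binaries fixed, so reported fluxes are the smallest scaling satisfying the
balances rather than an arbitrary vertex of [1, Max].

## Filtering and ranking

The MILP guarantees global stoichiometric feasibility but not
*bootstrapability*: the first reaction (or a supplying chain feeding it)
might need an intermediate that nothing can make from the pool. The filter
checks constructively for an execution order in which every reaction's
non-pool substrates were produced earlier; we chose this whole-chain check
over the weaker first-reaction-only reading because a candidate whose supply
chain is circular is just as unusable.

Survivors are ranked lexicographically:

| # | criterion | better |
|---|-----------|--------|
| 1 | number of active reactions | fewer |
| 2 | starts with a basis metabolite | yes |
| 3 | path reactions without ΔrG′m | fewer |
| 4 | kinetic-trap score Σ(ΔrG + \|ΔrG\|) | lower |
| 5 | total path ΔrG | lower |
| 6 | heterologous reactions | fewer |
| 7 | distinct cofactor species | fewer |

Criteria 3–5 run over the linear-path reactions Z′; 1, 6 and 7 over all
active reactions. The trap score doubles every endergonic step and ignores
exergonic ones, so it is zero exactly when no known step runs uphill.
Unknown energies contribute nothing to the sums and are charged to
criterion 3 instead. Criterion 6 counts *reactions* absent from the host
set (enzyme-to-reaction mappings are many-to-many, so reaction counting is
the unambiguous choice); with no host set, every active reaction is
heterologous. Full ties keep enumeration order.

**Side reactions** are our operationalisation of "host reactions that would
interfere in a lysate or permeabilized cell": any host reaction outside the
candidate that consumes a linear-path node, the start metabolite, a
supplying-reaction product or the target. Cofactors and excluded
metabolites do not trigger listings — they are not pathway carbon
intermediates.

## A worked example

```{r fig3}
net <- make_fig3_network()
net
sols <- enumerate_pathways(net, "P", max_solutions = 5)
sols[[1]]
```

The optimum is the three-arc chain M1 → M2 → M3 → P. Its last reaction
consumes the external metabolite M4, so supplying reaction R4 (pool
metabolite M5 → M4) joins the candidate. Two decoy start metabolites are
planted a step further away and never appear in the optimum.

```{r fig3-reports}
res <- cmd_rank(net, sols, host = c("R1", "R2"))
res$table
thermodynamic_profile(sols[[1]], net)
```

## Synthetic fixtures and the oracle

`generate_random_network()` plants a guaranteed-feasible path of known
length to the target before adding random decoys: side substrates are drawn
from the pool with probability 0.7 and otherwise from externals backed by a
planted supplying reaction, so supplying reactions actually occur in tests;
a configurable fraction of random reactions duplicates an existing arc,
exercising parallel realisers. Everything is reproducible from a single
seed.

`brute_force_pathways()` is an independent oracle: exhaustive DFS over
simple arc paths, enumeration of every covering reaction subset, and a
smallest-first search for supplying sets with an LP feasibility check.
Objectives are compared as exact integers (arcs·(|R|+1) + active count) so
tie classification can never fall to floating-point noise. The validation
suite checks on 50 seeded fixtures (8–12 metabolites — sizes chosen so the
exhaustive oracle itself stays exact and fast) that full MILP enumeration
returns precisely the oracle's minimum-objective candidate set.

What these fixtures do *not* emulate: realistic degree distributions,
multi-substrate stoichiometry beyond single side substrates, compartments,
or the scale of a genome-wide network (thousands of reactions). Passing
tests demonstrate correctness of the algorithms, not performance or
biological realism at database scale; on a pan-organism network the
built-in solver would need to be swapped for an industrial MILP solver
through the same abstract-model interface.

## Degenerate inputs and numerical choices

* A target in the metabolite pool is a configuration error (there is
  nothing to synthesise); a target with no incoming arc yields an empty
  result with a warning, not an error.
* Equation sides must be disjoint; a metabolite on both sides is a parse
  error naming the record.
* Reversibility threshold boundaries are sharp: |ΔrG| exactly at the
  threshold is irreversible.
* If exclusion pressure ever drives the model into an assignment that is
  not a simple chain (possible once all genuine paths are spent),
  enumeration treats it as exhaustion rather than failing.
* SBML identifiers outside the SId grammar are hex-escaped reversibly;
  the writer emits Level 3 Version 1 core and the bundled reader verifies
  round-trips structurally (no schema validator is bundled).

## Limitations

Enzyme kinetics (turnover numbers, Km, enzyme concentrations) are out of
scope, as are ΔrG estimation itself (energies are inputs), atom mapping,
K-shortest searches between two *fixed* metabolites, and live database
access: the package consumes files shaped like the KEGG/eQuilibrator
exports it was designed around.
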