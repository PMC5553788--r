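# pathcascade

Design and ranking of multi-enzyme biosynthesis pathways in
reaction-pair networks.

`pathcascade` is for biochemists and metabolic engineers planning
syntheses with in vitro enzyme cascades, cell hydrolysates or
permeabilized cells. Given KEGG-style reaction records, a curated
reaction-pair (arc) table, transformed reaction Gibbs energies and a few
curated metabolite lists, it reconstructs a directed metabolic network,
enumerates candidate synthesis pathways to a target metabolite, and
filters, ranks and documents the candidates.

## The model

The network is a set of *arcs* — directed substrate→product edges
derived from curated reaction pairs (main- and trans-pairs), with arcs
through cofactors removed to prevent meaningless shortcuts. Reaction
directionality follows ΔrG′m (1 mM, pH 7, 25 °C) with a 15 kJ/mol
threshold: near-equilibrium reactions are split into forward/backward
pairs, strongly endergonic ones are flipped, reactions without data stay
as written.

Path finding solves a mixed-integer linear program over binary arc
variables u_ij, binary reaction-activity variables z_r and continuous
fluxes v_r ∈ [1, Max]:

```
min  Σ u_ij + 1/(|R|+1) · Σ z_r
s.t. a simple connected arc chain from any start metabolite to the target
     (one arc into the target, none out of it; basis metabolites only as
      first node; degree balance elsewhere; no node entered twice)
     Σ_r S_mr v_r ≥ 0  for every non-pool metabolite m   (no uptake)
     Σ_r S_Pr v_r ≥ 1                                     (make product)
     z_r ≤ v_r ≤ Max·z_r ;  z_λ + z_μ ≤ 1 for reverse pairs
     Σ_r d_ijr z_r ≥ u_ij   (every chosen arc realised by a reaction)
```

No start metabolite is fixed in advance — the search finds suitable
starting points. A solution is a linear path plus the *supplying
reactions* that produce non-pool substrates consumed along it; the pair
(path, Z′) of the path and its realising reactions identifies a
candidate. Exclusion cuts stream distinct candidates in nondecreasing
objective order. Because the models are small, the package includes its
own exact MILP solver (two-phase simplex + branch-and-bound); candidates
are reproducible bit-for-bit across runs.

Surviving candidates are ranked lexicographically by seven criteria:
active-reaction count, basis-metabolite start, missing thermodynamic
data, kinetic-trap score Σ(ΔrG + |ΔrG|), total path ΔrG, heterologous
reactions and distinct cofactor species. Each candidate gets a
thermodynamic profile, an overall reactant balance, a host side-reaction
list and an SBML L3V1 file.

## Worked example

The bundled example network has a three-step chain from the start
metabolite M1 to the product P; the last step consumes an external
metabolite M4 that reaction R4 must supply from the pool, and two decoy
start metabolites sit one step too far away.

```r
library(pathcascade)
net <- make_fig3_network()
net
#> <metabolic_network> 11 metabolites, 8 directed reactions, 8 arcs
#>   pool: 5  external: 6  start: 3  basis: 1

sols <- enumerate_pathways(net, "P", max_solutions = 5)
sols[[1]]
#> <pathway_solution> M1 -> M2 -> M3 -> P
#>   path reactions: R1, R2, R3
#>   supplying: R4
#>   objective: 3.444444
```

The optimum uses 3 arcs and 4 active reactions (objective
3 + 4/9 ≈ 3.44: arc count dominates, active reactions tie-break). The
decoy route appears only as the second-best candidate:

```r
res <- cmd_rank(net, sols, host = c("R1", "R2"))
res$table
#>   rank start          path n_active_reactions starts_with_basis
#> 1    1    M1    M1>M2>M3>P                  4              TRUE
#> 2    2    D1 D1>D2>D3>M3>P                  5             FALSE
#>   n_reactions_missing_dg kinetic_trap_score total_dg n_heterologous
#> 1                      0                  0      -50              2
#> 2                      0                  0      -79              5
#>   n_cofactor_species
#> 1                  2
#> 2                  0

thermodynamic_profile(sols[[1]], net)
#>   step reaction substrate product  dg dg_known cumulative_dg
#> 1    1       R1        M1      M2 -20     TRUE           -20
#> 2    2       R2        M2      M3  -5     TRUE           -25
#> 3    3       R3        M3       P -25     TRUE           -50
```

A kinetic-trap score of 0 with monotonically dropping cumulative ΔrG
marks a thermodynamically smooth route; the M1 candidate wins on
pathway length (criterion 1) before any later criterion is consulted.

The same workflow runs from files:

```sh
pathcascade reconstruct --reactions reactions.keg --pairs pairs.tsv \
    --thermo thermo.tsv --compounds compounds.tsv --basis basis.txt \
    --cofactors cofactors.txt --excluded excluded.txt -o net.json
pathcascade find --network net.json --target P --max-solutions 20 -o cands.json
pathcascade rank --network net.json --candidates cands.json --host host.txt -o out/
```

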