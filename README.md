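# minprec — minimal stoichiometric precursor sets of metabolic networks

What must an organism take up from its environment, at the very least, to
make a given set of metabolites — a biomass pseudo-compound, an amino acid,
a drug precursor? Each inclusion-minimal answer is a **minimal precursor
set**: a smallest set of *source* compounds from which the *targets* can be
produced by a feasible flux through the reaction network. Enumerating *all*
of them, not just one, is what lets you predict alternative minimal growth
media, compare nutritional capabilities across strains, or reason about
cross-feeding in microbial communities.

`minprec` decides and exhaustively enumerates minimal precursor sets of a
metabolic network `N = (C, R)` with designated sources `X ⊆ C` and targets
`T ⊆ C`, under three flux models. Writing `S` for the stoichiometric matrix
(products positive, substrates negative) and `v ≥ 0` for a flux vector,
`X ⊆ X` is a **stoichiometric precursor set (SPS)** if there is `v` with

```
(Sv)_{C \ X} ≥ 0        (no compound outside X is consumed on balance)
(Sv)_T      > 0         (every target is strictly produced)
```

— the *accumulation* model. The *steady-state* model replaces `≥ 0` by
`= 0` on internal compounds; the *machinery-duplicating* model additionally
demands `(Sv)_j > 0` for every non-source substrate `j` of an active
reaction (it rejects catalytic cycles that only regenerate their carriers,
the way the Krebs cycle regenerates oxaloacetate).

Purely **topological precursor sets** (every needed compound is a source or
a product of a used reaction, quantities ignored) are a strict superset:
the package also enumerates those, and the gap between the two notions is
illustrated by the built-in example networks.

## Algorithms

* **Iterated MILP with exclusion cuts** (`enumerate_minimal_sps`, method
  `"milp"`) — one binary `b_j` per source gates its *source-pool* reaction
  (`b_j ≤ v_j ≤ U·b_j`); minimising `Σ b_j` subject to the flux model gives
  a minimum-cardinality solution; the cut `Σ_{j∈I} b_j ≤ |I|−1` removes a
  found solution `I` and all its supersets; iterate until infeasible. The
  result is exactly the antichain of all minimal solutions.
* **Combinatorial route** (`"combi"`) — every minimal stoichiometric
  factory decomposes into minimal *topological* factories of the
  many-to-one transform `Ψ(N)` (each multi-product reaction split into one
  single-product copy per product). Enumerate those factories, test unions
  of k = 1, 2, … of their source footprints for flux feasibility.
  Exponential in bad cases; provided as an independent cross-check.
* **Brute force** (`"brute"`) — test all `2^|X|` source subsets with the LP
  membership oracle, ascending by cardinality with monotone pruning.

No LP/MILP solver dependency: the package carries a small dense two-phase
simplex and a branch-and-bound layer (with indicator-style constraint
branching for the machinery-duplicating disjunctions), adequate for the
problem sizes it targets. `check_sps`, `check_s_factory`, `check_md_sps`,
`check_scs` (cut-set membership) and `reduce_to_minimal` expose the
individual decision oracles.

## Worked example

The built-in `topo_vs_stoich_network()` (three sources `p1, p2, p3`, one
target `t`, eight unit-coefficient reactions) separates topology from
stoichiometry:

```r
library(minprec)
net <- topo_vs_stoich_network()
enumerate_minimal_sps(net)
#> 2 minimal precursor set(s) [mode accumulate, method milp, exhausted]
#>   { p1 }
#>   { p2, p3 }

enumerate_minimal_tps(net)       # topological solutions differ!
#> [[1]]
#> [1] "p1"
#> [[2]]
#> [1] "p3"
```

`{p3}` is topologically sufficient but admits no feasible flux, and
`{p2, p3}` is invisible to topological minimality — both phenomena occur in
real networks. The flux certificate behind `{p1}` needs all four reactions
of the internal loop, including the `a -> b` recycling step a topological
factory can skip:

```r
s <- enumerate_minimal_sps(net)$solutions[[1]]
round(s$flux[s$flux > 1e-6], 3)
#>  r1  r2  r3  r4
#> 0.5 0.5 0.5 0.5
```

Under the machinery-duplicating model only the cycle-free route survives:

```r
enumerate_minimal_sps(net, sps_config(mode = "md"))
#> 1 minimal precursor set(s) [mode md, method milp, exhausted]
#>   { p2, p3 }
```

## Command line

```sh
Rscript inst/cli/minprec \
  --network net.txt --sources sources.txt --targets targets.txt \
  --mode accumulate --algorithm milp --output run1
```

reads a plain-text reaction list (`r1: 1.0 c1 + 2.0 c2 -> 1.0 c3`, `<=>`
for reversible; SBML also accepted), writes `run1.json` (solutions with
flux certificates), `run1.tsv` (one solution per row) and
`run1.manifest.json` (inputs, hashes, configuration, wall time). Exit code
0 = complete enumeration, 3 = partial (a limit was hit), 1 = error.
`--autosources` takes as sources every compound no irreversible reaction
produces.

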