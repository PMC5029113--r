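---
title: "Enumerating minimal stoichiometric precursor sets: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating minimal stoichiometric precursor sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minprec)
```

## The question and the three flux models

A metabolic network is a directed hypergraph: compounds are vertices, each
irreversible reaction an hyperarc from its substrate multiset to its
product multiset, with strictly positive stoichiometric coefficients on
both sides. Given *sources* $\mathcal{X}$ (compounds the environment may
offer) and *targets* $\mathcal{T}$ (what must be made — typically the
product of a biomass reaction), a set $X \subseteq \mathcal{X}$ is a
*stoichiometric precursor set* (SPS) if some flux $v \ge 0$ produces every
target strictly while no compound outside $X$ is consumed on balance:
$(Sv)_{\mathcal{C}\setminus X} \ge 0$, $(Sv)_{\mathcal{T}} > 0$, with $S$
the stoichiometric matrix. "Minimal" always means inclusion-minimal; the
complete answer to "what are the minimal media?" is the antichain of all
minimal SPSs.

Three variants of the second constraint are supported, selected by
`sps_config(mode = ...)`:

* **accumulate** (default): internal compounds may pile up
  ($\ge 0$) — the printed definition above.
* **steady-state**: internal compounds (neither sources nor targets) must
  balance exactly ($= 0$); targets keep $\ge 0$.
* **md** (machinery-duplicating): on top of the accumulate constraints,
  every non-source substrate $j$ of a flux-carrying reaction must itself be
  strictly net-produced, $(Sv)_{\mathcal{T} \cup Y} > 0$ with
  $Y = \mathrm{Subs}(F)\setminus X$ for the active set $F$. This model
  demands that the network replicate its own machinery; it rejects
  catalytic cycles that merely regenerate a carrier. The package's
  `krebs_toy_network()` — a three-reaction loop whose internal compounds
  have exactly zero net production at unit flux — is feasible from its one
  source under the first two models and infeasible under `md`, which is the
  clearest argument that `md` is too strict for Krebs-like chemistry.

Topological precursor sets (TPS) ignore quantities: $F$ is a topological
factory from $X$ when
$\mathcal{T} \cup \mathrm{Subs}(F) \subseteq \mathrm{Prod}(F) \cup X$.
Every SPS is a TPS; the converse fails, and minimal SPSs need not be unions
of minimal TPSs (`topo_vs_stoich_network()` exhibits both phenomena).

## Normal form

All analyses assume a *normalized* network (`normalize_network()`): every
reversible reaction split into `_fwd`/`_rev` copies, and no reaction
producing a source — a produced source $x$ is replaced as a source by a
dummy $x{\_}src$ together with $r{\_}src{\_}x : 1\,x{\_}src \to 1\,x$,
which changes nothing about what any source set can produce but makes
"source" and "produced compound" disjoint vocabularies. Reactions with a
compound on both sides are rejected at construction rather than
net-cancelled: the hypergraph model assumes disjoint sides, and silent
cancellation would alter the topological notions. User-supplied reactions
with an empty substrate side are rejected too (they would make the empty
set a precursor set of whatever they produce); the only zero-substrate
reactions are the source pools the package adds itself.

## The MILP engine

`enumerate_minimal_sps(method = "milp")` augments the network with one
*source-pool* reaction per source ($\emptyset \to 1\,x_j$) and a pooled
target ($\bar r : \sum_{t \in \mathcal{T}} 1\,t \to 1\,\bar t$, all
coefficients one), then iterates:

$$\min \sum_j b_j \quad \text{s.t.} \quad
(\bar S v)_{\bar t} \ge \epsilon,\;
\bar S v \ge 0,\;
b_j \le v_j \le U b_j,\;
0 \le v \le U,\; b_j \in \{0,1\}$$

A found solution with support $I$ is excluded — together with all its
supersets — by the cut $\sum_{j \in I} b_j \le |I| - 1$, and the loop stops
at the first infeasible program, which certifies completeness. Each
returned set is inclusion-minimal automatically (a feasible proper subset
would be unexcluded and cheaper), and the engine re-verifies this by
running `reduce_to_minimal()` on every solution — a no-op unless the solver
is broken, in which case the run aborts rather than return a wrong family.
The lower link `b_j \le v_j` deliberately forces at least one unit of
supply from every chosen source, so "used" is never a numerically empty
gesture.

Tunables, all in `sps_config()` with units of flux per arbitrary time:
`epsilon = 0.5` (stand-in for "strictly positive" target production),
`eps_bar = 0.5` (same, for machinery-duplicating net production),
`upper_bound = U = 1000` (per-flux cap, also the big-M scale),
`delta = 0.001` (flux floor for reactions asserted active in
`check_s_factory()`), `support_tol = 1e-6` (activity threshold defining a
certificate's support). The `epsilon`/`eps_bar`/`U` defaults are the
constants this family of methods is conventionally run with; verdicts are
invariant to their exact values as long as
$\epsilon, \bar\epsilon \ll U$ (feasible fluxes rescale — property-tested),
and `target_level = "max"` replaces $\epsilon$ by the LP-maximal target
yield when one wants only the precursor sets supporting maximal biomass.

### Membership semantics under a finite flux cap

The textbook membership test solves an LP maximising pooled-target
production with source consumption unconstrained and calls $X$ an SPS when
the optimum is positive. With the finite cap $U$ that the MILP needs, "any
positive optimum" and "at least $\epsilon$" can disagree on networks whose
stoichiometry attenuates flux multiplicatively (producing one target unit
may need more than $U$ units upstream). `check_sps()` therefore pools the
sources of $X$ (supply $\le U$ like every flux) and applies the same
$\epsilon$ threshold as the enumeration MILP: all engines — MILP, combi,
brute force — decide the *identical* bounded-producibility question, which
is what makes their three-way equivalence a meaningful test rather than a
coincidence of tolerances. For genome-scale use the practical reading of a
verdict is "producible at level $\epsilon$ with every flux below $U$".

A corollary of taking the definitions seriously: networks containing an
autocatalytic subnetwork (a cycle with a net-amplifying coefficient, e.g.
$m \to 2m'$, $m' \to m$) have the *empty set* as their unique minimal
precursor set under the accumulate model. The MILP finds this naturally;
the brute-force oracle scans subsets starting at cardinality zero for the
same reason.

### Machinery duplication without big-M

The published MILP encoding of the machinery-duplicating disjunction
$(\bar Sv)_j > 0 \vee \bigwedge_{i \in Q_j} v_i = 0$ (with $Q_j$ the
consumers of $j$) uses an indicator binary $E_j$ and big-M rows with
$D_j = U\,|Q_j|$. The LP relaxation of that encoding is extremely weak —
fractional $E_j$ of order $\bar\epsilon / D_j$ satisfy it while
constraining nothing — and branch-and-bound over the $E_j$ degenerates into
near-exhaustive search exactly when proving that no further solution
exists. Production solvers avoid this with native indicator constraints;
this package does the equivalent inside its own branch-and-bound: a node
whose LP optimum violates a disjunction is split into one child enforcing
$(\bar Sv)_j \ge \bar\epsilon$ and one child fixing all consumers of $j$
to zero. Both children satisfy the disjunction permanently, the tree stays
finite, and no $E_j$ variables or big-M rows exist at all. The same
reasoning fixes a second big-M trap: when branching sets $b_j = 0$, the
bound $v_j \le U b_j$ leaves a residual infeasibility of order $v/U$ that
can slip under LP feasibility tolerances, so the solver propagates
$b_j = 0 \Rightarrow v_{\mathrm{pool}_j} = 0$ explicitly.

## The combinatorial route

In the many-to-one transform $\Psi(\mathcal{N})$ (each reaction with $k$
products replaced by $k$ single-product copies sharing the substrate side),
minimal topological factories admit a clean local characterisation: every
non-source substrate — and every produced target — has *exactly one*
producer in the set, and every product has a hypergraph path to a target
inside the set. (The unique-producer condition must include produced
targets: a second producer of a target has a single product in a
many-to-one network and is therefore always removable. The package's
validator uses this corrected reading; an exhaustive test over all subsets
of the transformed example networks distinguishes the two readings and
confirms the correction.) `enumerate_mto_factories()` enumerates these
factories by backward branching from the targets, picking at each step the
lexicographically smallest unproduced compound for reproducibility.

Because every minimal stoichiometric factory under the accumulate model is
a union of such factories, testing unions of $k = 1, 2, \dots$ factory
footprints for flux feasibility (`combi_enumerate()`) is a complete
enumeration strategy. Unions are memoised by footprint and pruned against
already-found solutions; the scan stops when a level contributes no new
union (provably nothing new can appear later) or the factory count is
exhausted. The same decomposition argument goes through for the
machinery-duplicating model (the downstream set removed in the truncation
argument neither produces targets nor feeds surviving reactions). It
**fails for exact steady state**: forced "disposal" of by-products can make
a source necessary that no factory footprint contains. The test suite pins
a concrete 22-reaction counterexample whose minimal steady-state solution
`{x1, x3, x5}` contains only the footprint `{x3}`; `combi_enumerate()`
warns in this mode, and remains sound (everything it returns is a true
minimal solution) but possibly incomplete. The MILP engine has no such
restriction — and is the practical choice anyway: the example networks
built by `decoy_factories_network(n)` (factories that can never carry
flux) and `combination_blowup_network(n)` (a solution visible only at
$k = n$) show why the combinatorial route is kept as a cross-check, not as
the engine.

## What the synthetic data does and does not establish

`random_network()` emulates small metabolisms: random hyperarcs with 1–2
substrates/products, coefficients drawn from $\{1, 1, 1, 2\}$ (mostly
unit, occasionally doubling — enough to create topological/stoichiometric
gaps and mild amplification), 8 internal compounds, 14 reactions, 4
sources, one target, rejection-sampled until the target is in the forward
closure of the sources so that every instance has at least one candidate
solution. Sizes are capped (≤ 10 sources) to keep the $2^{|\mathcal{X}|}$
brute-force oracle exact and fast. A green three-way equivalence over this
corpus establishes that the MILP engine, the factory-combination route and
definition-level subset scanning compute the same families *on networks of
this scale and density*; it says nothing about numerical behaviour at
genome scale (thousands of reactions, coefficients spanning orders of
magnitude), where a production LP solver and looser tolerances would be
appropriate. Real networks also have features the generator does not
imitate: reversibility declared per reaction, compartments, cofactor
ubiquity, and biomass reactions with dozens of substrates.

## Numerical choices and degenerate inputs

* Strict inequalities are represented by the $\epsilon$ / $\bar\epsilon$ /
  `delta` floors above; supports by `support_tol` (absolute, aligned with
  typical MILP integer-feasibility tolerances).
* The internal simplex is a dense two-phase tableau method: Dantzig
  pricing, switching to Bland's rule after a long degenerate stall (exact
  balance rows make these LPs highly degenerate; Bland-from-the-start was
  measured an order of magnitude slower, Dantzig-only can cycle). Phase-1
  acceptance is an *absolute* artificial-sum threshold ($10^{-6}$): with
  big-M rows in the system, a threshold relative to $\max |b|$ would admit
  slightly-infeasible systems, which is precisely the failure mode the
  branch-and-bound cannot tolerate.
* Every feasibility verdict returned with a witness is re-verified against
  the raw constraint system; a violation aborts with an internal error
  instead of propagating a wrong answer.
* A compound consumed by nobody needs no machinery-duplicating disjunction
  (its net production may legitimately be zero); reactions with an empty
  product side are accepted with a warning and simply never help a
  factory; a target that is also a source is rejected unless explicitly
  allowed.
* Ties between equal-cardinality MILP optima are left to deterministic
  depth-first search order (zero branch first), so runs are reproducible
  but the *representative* order of solutions carries no meaning — the
  solution *set* is what is specified, and it is seed-independent.

## Known limitations

* The simplex/branch-and-bound pair is built for tens of variables; no
  warm starts, no sparsity. Genome-scale networks will parse and the CLI
  will run, but runtimes are not benchmarked and a network of thousands of
  reactions is outside the tested envelope.
* Joint enumeration of precursor sets and cut sets via monotone
  dualization is out of scope; only the membership test `check_scs()` is
  provided.
* `combi_enumerate()` is exponential by nature and incomplete under exact
  steady state (see above).
* SBML import is deliberately minimal (species, reactions, stoichiometries,
  reversibility, boundary flags); gene–protein–reaction rules,
  compartments and units are ignored.
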