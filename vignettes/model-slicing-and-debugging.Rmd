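---
title: "Slicing and debugging stochastic SBML models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slicing and debugging stochastic SBML models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochslice)
```

## The problem

Genome-scale reaction-network reconstructions encoded in SBML routinely
arrive in a state that cannot be simulated: initial amounts are missing,
kinetic laws are absent, and attributes such as `reversible` are left unset
with level-dependent default semantics. When a stochastic simulation of such
a model misbehaves, the modeler faces two compounding problems: the defect
could be stochastic noise or a genuine model flaw, and the model is far too
large to inspect whole. stochslice treats this as a program-diagnosis
problem: extract the sub-model relevant to one species of interest (a
*slice*, by analogy with program slicing), simulate it with a Gillespie
engine, and interrogate the simulation with the primitives of a software
debugger — breakpoints, watches, runtime edits and deadlock reports.

## The reaction graph

All analysis rests on a directed dependency graph over *reaction
directions*. Every irreversible reaction contributes one node; every
reversible reaction contributes two (the backward direction carries the
`_rev` suffix and mirrored stoichiometry; reversible reactions still count
once in all complexity statistics). An edge `u -> r` exists exactly when
some species is a product of `u` and a reactant of `r`, with three
exclusions:

* species on the *cofactor list* never form edges. Ubiquitous carriers —
  by default H+, AMP, ADP, ATP, CoA, NAD, NADH, NADP, NADPH and phosphate —
  take part in so many reactions that including them connects essentially
  everything to everything and fabricates pathways sharing no actual
  material flow. Genome-scale models use compartment-suffixed ids, so an
  editable alias table maps the canonical names onto the model's
  convention; matching is by exact id after aliasing, never by display
  name.
* the two directions of one reversible reaction are never linked to each
  other (the link would be a contentless two-cycle);
* modifier species create no edges — dependency is defined through
  reactant/product roles only.

Edges are duplicate-free and the structure is symmetric by construction
(`u` upstream of `r` iff `r` downstream of `u`). Boundary-condition species
form edges normally; the only exclusion mechanism is the cofactor list.

```{r graph}
m <- make_fixture("MINI_GLYCOLYSIS")
graph <- build_graph(expand_directions(m), cofactors = attr(m, "cofactors"))
graph
```

## Model slicing

A slice is built for a *sink* species, optionally constrained to a
*source*. Enumeration walks the graph upstream, depth-first, from every
reaction that produces the sink. Each maximal simple path — no directed
reaction repeats within a path, which is also the cycle guard — is a
*pathway candidate*. When a source is given, a reaction whose reactants are
all accounted for (the source itself, a cofactor, or a boundary species)
also terminates a path, and only candidates rooted at such reactions are
kept; candidates whose reaction set duplicates another's are dropped as
completely redundant. The traversal order (depth-first, children in
lexicographic order) is a design choice made for determinism; the candidate
*set* does not depend on it.

The slice's reactions are the union of the candidates' base reactions plus
every *first-degree* downstream reaction consuming a species that lies on a
candidate: those consumers compete for the sink's precursors, so they shape
its trajectory, whereas reactions one step further removed do not act on
any slice species and are cleaved. Two deliberate boundaries of that
expansion: it never recurses from species that only the expansion itself
introduced (otherwise the whole connected component would be pulled back
in), and cofactor species never qualify a reaction for expansion — which is
precisely why globally ATP-consuming reactions are absent from an
ATP-production slice and must be sought in the parent model when a merged
slice underperforms (`missing_link_report()` and a set difference against
the parent's consumer list are the supplied tools).

```{r slice}
sl <- slice_model(m, graph, sink = "pyr", source = "glc")
sl
complexity_report(m, sl)$pct_reduction
```

An optional state-dependent mode (`state =` argument) drops candidates
whose root reaction has zero propensity in a supplied state, reflecting
that at different time points different roots are live; the default slice
deliberately ignores state so that its output is a property of the model
alone.

Slices export as standalone SBML documents (`export_slice()` +
`write_model()`) and merge back with `merge_slice()`, which overwrites
kinetics, reversibility and initial amounts for ids present in the edited
document, appends genuinely new ids, and reports the changed-id set.

## SBML dialect decisions

All format decisions live in the I/O layer:

* **Reversibility.** Level 2 semantics default a missing `reversible`
  attribute to true; in Level 3 the attribute is required, so a missing one
  is a model defect. The loader records the flag as unset either way and
  warns (`WARN REVERSIBLE_UNSET <id> ...`); `resolve_reversibility()`
  repairs with a configurable default (true) plus per-reaction overrides.
  Nothing downstream accepts unset flags — a wrong flag silently deletes
  graph edges, which is exactly the class of defect the candidate
  enumeration is designed to surface.
* **Missing amounts** default to 0 with a warning rather than an error:
  shipping without amounts is the normal state of reconstructions.
* **Missing kinetics** are recorded as absent, never invented;
  `assign_default_kinetics(model, k = 0.1)` implements the standard
  bootstrap of giving every bare reaction the same small constant.
* **Non-integer stoichiometries** (biomass reactions) are rounded *up* with
  a warning, because the stochastic engine keeps integer molecule counts.
* **Kinetic-law expressions** are kept as parsed rate expressions
  (arithmetic MathML subset; local parameters are substituted by value) and
  evaluated on raw amounts with no volume conversion — the source models
  carry no consistent volume semantics, so amounts are treated as substance
  counts throughout. Negative evaluations are clamped to 0 with a warning.
* Identity is the SBML `id` attribute; display names play no role.

## The stochastic engine

Simulation is Gillespie's direct method: initialize at `t = 0` from the
declared amounts; per iteration compute each direction's *reaction weight*
(propensity) — for mass action `k * prod(choose(n_i, s_i))`, the
combinatorial count of distinct reactant sets, zero whenever any reactant
is short; draw the waiting time exponentially at total rate `a0` and the
reaction with probability `a_r / a0`; apply the stoichiometry and iterate.
Numerical determinism is pinned down explicitly: reactions enter the
cumulative sum in lexicographic id order, one seeded generator drives a
run, and replicate `i` of an ensemble uses `seed + i - 1` unless explicit
seeds are given — identical inputs give bit-identical event logs.

Deadlock is a first-class result, not an error: `a0 == 0` yields reason
`NO_AVAILABLE_REACTANTS`, and `0 < a0 < eps` yields `RATES_TOO_LOW`
(default `eps = 1e-12`, i.e. a mean waiting time of 10^12 time units —
beyond any practical horizon; configurable). Boundary-condition species are
never changed by firings, in keeping with SBML semantics, though their
production counters still accumulate. After a deadlock the state is
provably constant, so a finite-horizon trajectory reports coverage to the
horizon, which matters for stabilization detection below.

```{r ssa}
traj <- simulate_ssa(m, max_steps = 2000, seed = 1)
traj
tail(sort(traj$produced), 4)
```

`multi_simulate()` runs replicate trajectories and resamples them on a
common grid (last-observation-carried-forward, default 1 time unit) into a
mean/SD envelope — the substrate for outlier breakpoints.

## Predictive weights

A reaction whose reactants are not yet available has zero propensity, but
it can still be the reaction the modeler cares about. The predictive weight
is a forward-algorithm-style aggregate: available reactions carry their
*normalized* weight `N(r) = a_r / a0`; a blocked reaction receives
`sum over upstream u of alpha(u) * beta(u -> r)`, where
`beta(u -> r) = k_r / sum of k_d over u's downstream competitors` is the
branch share computed from rate constants (rate expressions are evaluated
at unit amounts as a static proxy). Raw propensities can exceed 1, and
multiplying such weights along a path would yield a "probability" larger
than its factors; normalizing both factors to shares *before*
multiplication is what keeps every value in `[0, 1]`. The recursion is
memoized (linear in edges) and nodes on the active recursion stack
contribute 0, so cycles terminate. The value is a heuristic reachability
score, not an exact first-passage probability.

Recomputation is triggered when a step produces a brand-new metabolite
(`on_new_metabolite()`), the only event that can unblock a reaction,
rather than on every firing; per-step recomputation remains available by
simply calling `predictive_weights()` in a stepping loop.

## Debugging

`debug_session()` wraps the same engine core, owning its RNG state so that
a session halted at breakpoints and resumed produces exactly the event log
of an uninterrupted run — breakpoints are observation-only by construction.
Reaction breakpoints fire *before* the selected reaction executes, so the
pending instruction can be skipped (`skip_instruction()` excludes it for
one selection round; if nothing else is available that is an immediate,
honest deadlock). Condition breakpoints use a deliberately tiny predicate
language — comparisons, boolean operators and arithmetic over
`amount(id)`, `produced(id)`, `param(id)` and `t` — small enough that every
halt is auditable; general R expressions are rejected. Outlier breakpoints
compare the live run against an ensemble envelope at grid times, scoring
each grid point with the value the run actually held at that time.
`modify_session()` edits amounts, parameters or rate constants at a halt
(negative amounts rejected), which is both the parameter-estimation loop —
compare competing weights at a breakpoint, adjust `k`, resume — and the
deadlock-escape hatch. "Reaction ordering" control is realized as
per-reaction disable plus one-round skip, the only order controls
compatible with stochastic selection.

```{r debug}
s <- debug_session(m, seed = 4)
add_breakpoint(s, reaction = "R_PGM")
run_until_break(s)
head(session_weights(s), 4)
```

## Comparison metrics

For scoring a reduced or sliced model against its original on a watched
species: model size is components (reactions + species); *stabilization*
is the first integer time unit from which the amount stays within 1%
(relative to the amount there, floored at 1 to survive zero plateaus) over
the following 10 time units, on a 1-time-unit grid; the *behavior
difference* is the sum of the two percentage differences — stabilization
time and stabilization amount — taken relative to the original model.
Relative-to-original is the only reading under which the published figures
for this metric are internally consistent, and it is what
`behavior_difference()` implements; a trajectory that never stabilizes is
reported as such and refused by the difference, never coerced.
`compare_report()` packages the loop; runtime and memory columns are
deliberately out of scope as hardware-bound.

```{r metrics}
behavior_difference(c(80, 375), c(10, 250))
```

## What the fixtures emulate — and what they do not

`make_fixture()` provides the topologies every algorithm needs: chains,
branches, cycles, the diamond (two disjoint routes to a sink), the three
slicing evaluation cases (pure upstream; first- versus second-degree
downstream; peer branches), and `MINI_GLYCOLYSIS`, a 10-reaction
glycolysis-shaped chain with two ATP-consuming priming steps, two
ATP-generating payoff steps, NAD recycling and the standard cofactors. Its
defaults were chosen once as a realistic small instance: 8 glucose, an ATP
stake of 2 against an ADP pool of 20, 10 NAD, 30 phosphate; the
second priming step carries a tenfold rate constant so that a primed hexose
tends to be carried through to payoff rather than the stake being spent
twice at the top of the pathway — with a stake of 2, spending both on the
first step before any payoff is a genuine (and intended) deadlock mode of
the topology. The fixture reproduces the qualitative signature of the
pathway: with no ATP stake the model deadlocks on its first selection;
with a small stake it turns a net ATP profit.

`make_random_model()` generates connected mass-action networks (chain
backbone plus random reactions, capped at 100 nodes) as the substrate for
property tests, where package algorithms are checked against brute-force
oracles: a triple loop over (producer, consumer, species) for graph edges,
and exhaustive simple-path enumeration for candidates.

What passing these tests does *not* show: fixtures are small, mass-action
only, and have none of the annotation noise of curated models (unit
declarations, compartment volume conventions, fractional biomass
stoichiometry at scale). Genome-scale behavior — candidate counts in the
thousands, slice sizes, repaired-reversibility diagnostics on real
glycolysis reactions — exercises the same code paths but depends on the
specific accession files, which are not redistributed here; the test suite
documents where to place them.

## Problem sizes and numerical choices

The shipped tests run chains and random models up to ~15 reactions for
exact oracle comparisons, 10,000-step runs for distributional checks
(selection frequencies and waiting-time means within three standard
errors), and 11–100-replicate ensembles on small fixtures — sizes chosen so
the full suite documents the engine's statistical behavior in seconds.
Ties and degenerate inputs are pinned: empty models build empty graphs; an
unreachable sink is a diagnosed failure ("sink unreachable"), distinct
from an unknown id; horizon 0 is a valid, empty, completed run; a
zero-amount start is an immediate `NO_AVAILABLE_REACTANTS` deadlock.

## Known limitations

* No SBML events, assignment/rate/algebraic rules, function definitions, or
  packages (fbc, comp); kinetic laws are honored only as arithmetic
  expressions.
* No tau-leaping or hybrid acceleration; genome-scale simulation at full
  length is outside the engine's intended envelope (slices are the point).
* Predictive weights are heuristic; the branch share uses static rate
  constants, not hypothetical post-firing states.
* Candidate enumeration is exponential in adverse topologies; a
  `max_candidates` guard fails loudly rather than silently truncating.
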