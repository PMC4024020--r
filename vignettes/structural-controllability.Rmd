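---
title: "Structural controllability analysis of metabolic networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural controllability analysis of metabolic networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netctrl)
```

This vignette is the package's account of the science it implements: the
models, the tunable parameters, the numerical choices, and the
limitations a user should keep in mind.

## From reactions to a directed network

A compartmentalized metabolic model is a list of reactions over
metabolites written `name[compartment]`; the same chemical species in two
compartments is two distinct nodes. The network construction rule is
purely topological: for every reaction, a directed link runs from each
substrate to each product. Stoichiometric coefficients are deliberately
ignored (the analysis is structural, not quantitative), and a directed
pair induced by several reactions is a single link that remembers all its
inducing reactions — so link-level annotations (reaction class, transport
status) can be multi-valued.

Two construction choices are not forced by the rule and are therefore
flags:

* **Reversible reactions** expand to links in both directions by default
  (`expand_reversible = TRUE`). A reversible reaction genuinely allows
  influence both ways; users who prefer the conservative single
  orientation can disable the expansion.
* **Self-loops** (a metabolite that is substrate and product of the same
  reaction) are retained in the network and flagged, but excluded from
  all matching computations by default: a self-loop trivially matches its
  own node and carries no influence between distinct metabolites. In the
  link-robustness classification a self-loop is its own alternating
  cycle, hence classified ordinary.

## Driver metabolites and maximum matchings

The controllability machinery rests on the bipartite split of the
directed network: each node `x` becomes an out-copy `x⁺` and an in-copy
`x⁻`, each link `x → y` an undirected edge `(x⁺, y⁻)`. A matching of this
graph is a set of links sharing no start and no end nodes; the nodes
whose in-copy a maximum matching leaves unmatched are the driver nodes,
and controlling each of them independently suffices to steer the whole
network. The driver count is `max(N − |M*|, 1)`: even a perfectly matched
network needs one input, and in that case the package deterministically
nominates the first node in canonical id order (a documented convention —
the genome-scale networks this analysis targets never reach a perfect
matching).

The matcher is Hopcroft–Karp, implemented in the package rather than
delegated, for one reason: the sampling handle. Maximum matchings are far
from unique, and which one the algorithm finds depends on the order edges
are considered. `sample_mdms()` shuffles the edge list with a seeded RNG
before each run, collects the induced driver sets, and de-duplicates *at
the driver-set level* (two different matchings often induce the same
MDMS; both tallies are recorded in the sample's attributes). Enumerating
all maximum matchings is #P-complete, so sampling is the only scalable
route; the sampler stops at the requested number of distinct MDMSs or at
an attempt budget (default ten times the request), returning what it
found with a warning — on small or rigid networks the warning simply
means the MDMS space was exhausted and the frequencies are exact.

Driver frequencies `f_d` (fraction of retained MDMSs containing the
node) are classified critical (`f_d = 1`), high-frequency
(`0.6 ≤ f_d < 1`) or low-frequency (`0 ≤ f_d < 0.6`). The boundaries are
honoured exactly by comparing integer counts (`5·count ≥ 3·n`), never
floating-point ratios. The denominator is the number of *distinct* MDMSs
retained.

## Exact node classes without enumeration

Classifying every node as a driver in all / some / none of the MDMSs
(critical / intermittent / redundant) does not require enumeration. Two
structural facts give an exact linear-time classification from a single
maximum matching:

1. an in-copy with at least one incoming link is matched in *some*
   maximum matching (exchange argument: if `v⁻` is free and its neighbour
   `u⁺` matched elsewhere, rematching `u⁺` to `v⁻` preserves maximality),
   so **critical ⇔ in-degree zero**;
2. a matched in-copy is avoidable (the node drives some MDMS) exactly
   when it is reachable from a free in-copy along an alternating path —
   one multi-source BFS in the orientation "free edges from in-copies,
   matching edges from out-copies".

The test suite verifies this classification against brute-force
enumeration of all maximum matchings on every fixture and on batches of
random graphs. One convention is worth noting: a perfectly matched
network has *no* structural drivers, so all its nodes classify redundant;
the single nominated driver of the MDMS convention does not bleed into
the class definition.

The **control mode** compares the redundant fraction `n_r` with the same
fraction `n_r^T` of the transposed network: `Δn_r > 0` is centralized,
`Δn_r < 0` distributed. `Δn_r = 0` is reported as *indeterminate* — only
the two strict inequalities are defined, and forcing a tie into either
camp would manufacture a result.

## Link robustness classes

A link is critical (in every maximum matching — its loss increases the
driver count), redundant (in none — freely removable), or ordinary (in
some). Régin's orientation argument classifies all links from one
matching: orient matching edges `x⁺ → y⁻` and free edges `y⁻ → x⁺`
(and the reverse in a second orientation); a link is ordinary iff it lies
on a directed path from a free node in either orientation or inside a
strongly connected component (an alternating cycle). The two orientations
are mutual reverses, so their SCC partitions must coincide — the package
computes both and asserts equality as a live cross-check. Remaining
matched links are critical, remaining free links redundant. The result is
invariant to which maximum matching was drawn; the tests verify both the
invariance (repeated runs under shuffled edge orders) and the classes
themselves (brute force on small graphs), plus the operational meaning:
deleting a critical link drops the matching size by one, deleting any
other link does not.

For enrichment, links carry the class labels of their inducing reactions.
A link induced by reactions of different classes counts once under each
label (fractions then use label occurrences as denominator); a strict
count restricted to uniquely-labelled links is reported alongside, since
no single convention is canonical for multi-label links.

## Modules by simulated annealing, roles by cartography

Modularity is evaluated on the undirected simple projection (directions
dropped, reciprocal links merged, self-loops removed — the modularity
definition and the classical cartography are undirected):

$$M = \sum_{s=1}^{N_M}\left[\frac{l_s}{L} - \left(\frac{d_s}{2L}\right)^2\right]$$

with `L` the undirected link count, `l_s` the links within module `s`,
`d_s` its degree sum. The single-module partition scores exactly 0, which
the acceptance script recomputes as the package's frozen reference
quantity.

The optimiser anneals `C = −M`: at each temperature it attempts `f·S²`
single-node moves and `f·S` collective moves, accepting a proposal with
probability 1 when `C` does not increase and `exp(−ΔC/T)` otherwise, then
cools geometrically, `T' = cT`. Defaults are `f = 1` and `c = 0.965`.
Choices the classical recipe leaves open, fixed here as package policy:

* **Initial temperature.** No standard value exists; the package calibrates
  `T0` from a pre-pass of random single-node proposals so that roughly
  90 % of uphill moves would be accepted initially (median uphill ΔC
  divided by `ln(1/0.9)`), overridable in `sa_config()`.
* **Stop criterion.** "Until T reaches 0" is not finite for geometric
  cooling; the package stops at `T < 10⁻⁴·T0` or after three consecutive
  temperatures without a single accepted move.
* **Collective moves.** Merge joins two random modules (its ΔM is closed
  form). Split bisects a random module at random, refines the bisection
  with up to two greedy single-node passes, and subjects the whole split
  to the Metropolis rule. This is a lighter refinement than a full inner
  annealing on the module subgraph; recovery benchmarks (below) show it
  suffices at the scales the package targets.
* **Guarantee.** The best partition seen is returned and is never worse
  than the single-module baseline (`M ≥ 0`).

Roles use the within-module degree z-score (population standard
deviation; a module with zero spread gives all its nodes `z = 0` rather
than NaN) and the participation coefficient
`P = 1 − Σ_s (k_is/k_i)²` (isolated nodes: `P = 0`, non-hub). The role
thresholds are the classical cartography boundaries, inclusive as
stated: hubs at `z ≥ 2.5`; non-hubs split at `P ≤ 0.05 / 0.62 / 0.80`
(R1–R4), hubs at `P ≤ 0.30 / 0.75` (R5–R7). Role stability across
repeated annealing runs and the role composition of driver sets above a
sweeping frequency threshold `f_dt` are one-line wrappers over these
primitives.

Weighted modularity is stubbed out deliberately: the pipeline's networks
carry no link weights, and implementing an untestable variant would be
decoration.

## Centralities

Betweenness follows the classical directed definition (unnormalized,
endpoints excluded). The closeness family is implemented exactly as the
reciprocal-distance sums `Σ 1/d` (the harmonic form, which handles
unreachable pairs by a natural zero contribution — important in metabolic
networks, which are far from strongly connected): out-closeness over
`d(v,i)`, in-closeness over `d(i,v)`, and plain closeness over the
undirected projection. A `closeness = "classical"` switch offers
`1/Σd` for comparison. Tertile binning sorts by score with ties broken by
node id and keeps any tie group that straddles a cut entirely in the
lower bin — the one unstated choice in "three sets of similar sizes",
made deterministic and recorded. Fraction profiles of a node set across
the tertiles export their counts for the chi-square test.

## Chi-square enrichment

The goodness-of-fit statistic is `χ² = Σ(O_i − E_i)²/E_i` with expected
counts `E_i = p_i·ΣO_i` from *expected percentages*. The percentages are
used exactly as supplied — reported percentage sets are typically
rounded and sum to 0.999–1.0001, and renormalizing them would change the
statistic in the second decimal; the tolerance on the sum is 0.002.
Critical values come from `qchisq`, not a lookup table, and the decision
is `χ² ≥` critical value at `N − 1` degrees of freedom.

## The synthetic generator: what it emulates, and what not

`generate_reactions()` draws reaction sets with the structural features
the analysis depends on: a designated extracellular compartment; boundary
metabolites that appear only as substrates (each is given at least one
uptake reaction, so every boundary metabolite is a zero-in-degree node
and hence provably a critical driver downstream — the property the tests
lean on); transport reactions crossing compartments; a three-class
reaction labelling; and substrate/product counts from a geometric
distribution truncated to 1–4 (small multi-substrate reactions). The
default class mix (60/15/25 % core-high/core-moderate/non-core) and
transport share (~20 % of reactions) mirror the whole-network composition
reported for curated liver reconstructions, and the default size
(100 metabolites, 135 reactions) keeps the reaction-to-metabolite ratio
of such models at desk scale. Reactions touching boundary metabolites are
forced irreversible; other reactions are reversible with probability 0.1
(a generator choice with no canonical value).

What the generator does *not* emulate: the true degree sequence, pathway
structure, or stoichiometry of any real reconstruction. Passing tests on
generated models therefore demonstrate correctness of the algorithms and
of the structural guarantees (boundary ⇒ critical, class invariances),
not biological conclusions about any particular organism. One visible
consequence: at the default density the sampled MDMS is often unique
(every non-source in-copy is matchable in only one way at optimum),
whereas real reconstructions have thousands of distinct MDMSs; sparser
settings (e.g. 60 metabolites, 45 reactions) exercise the
high-/low-frequency classes.

`generate_planted_network()` is the standard planted-partition benchmark
(directed links within/between planted modules at two probabilities),
used for annealer recovery tests: two disjoint 10-cliques are recovered
(`M = 0.5`) in ≥ 95 % of seeded runs, and 4-module planted graphs reach
normalized mutual information ≥ 0.9 against the planted labels.

## Problem sizes and reproducibility

The package's own test battery runs brute-force cross-checks on graphs of
up to 8 nodes (where enumerating all matchings is trivial), batches of
200 random networks for the driver-count identity, and annealer
benchmarks on 20–40 node graphs — sizes chosen so the full suite
completes in about a minute while still exercising every code path.
Every stochastic function takes an explicit seed, restores the caller's
RNG state, and records the seed in its output; `run_full_analysis()`
writes all seeds into `summary.json`, so any reported number can be
regenerated from the summary alone.

## Known limitations

* Structural controllability treats all links as independent free
  parameters; mass-balance constraints, which correlate link weights
  within a reaction, are outside its scope (as they are for the whole
  approach, not just this implementation).
* The annealer's split move uses greedy refinement rather than a nested
  annealing; on networks far larger or more entangled than the tested
  scales a full inner annealing could find deeper optima.
* `#P`-hardness means driver frequencies on large networks are estimates
  whose accuracy depends on the sampling budget; the package reports
  distinct-matching and distinct-MDMS tallies so users can judge
  saturation.
* SBML input and stoichiometric (flux-balance) analysis are non-goals;
  the reaction-list dialect and edge lists are the supported inputs.
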