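---
title: "Diversity timescales of neutral evolution on graphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity timescales of neutral evolution on graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evodiv)
```

## The model

A population of `N` haploid individuals occupies the vertices of a strongly
connected directed graph `G = (V, E)`; an edge `(u, v)` means the offspring
of the individual at `u` may replace the individual at `v`. All types are
selectively neutral and there is no mutation. Each time step one ordered
replacement event happens:

* **bd updating** — a birth vertex `u` is chosen uniformly from `V`, then a
  death vertex `v` uniformly from the out-neighbors of `u`; the event
  `(u, v)` has probability `1/(N deg+(u))`.
* **db updating** — a death vertex `v` is chosen uniformly from `V`, then a
  parent `u` uniformly from the in-neighbors of `v`; probability
  `1/(N deg−(v))`.

A configuration is a vector `x = (x1, …, xN)` of type labels. The process
starts at maximal diversity (`xi = i`) and ends at one of the `N`
homogeneous absorbing states; the quantity of interest is the expected
number of steps until absorption, `T_N`. On a `D`-regular graph both rules
assign every ordered edge event the probability `1/(N D)`, so the two
dynamics induce the same Markov chain and identical absorption times — the
rule only matters on irregular graphs.

Two modelling conventions matter for every number the package produces and
are fixed deliberately:

* **Time is counted in replacement events**, one event per step. A
  "generation" is `N` steps; `summary()` of an absorption fit reports the
  conversion, and the CLI offers a `--generations` column, but all stored
  times are steps. No-change events (an offspring landing on its own type,
  or a self-loop self-replacement on the complete graph) consume a step —
  the closed forms below count them, so the simulator must too.
* **Vertices are indexed `1..N`** inside R, matching the language and
  igraph. The on-disk formats (graph6, TSV edge lists) use the standard
  0-based indices; conversion happens only at the I/O boundary.

## Exact computation

### Full chain and partition lumping

The expected absorption times solve the first-step system `τ(x) = 0` on
homogeneous states and `τ(x) = 1 + Σ_{x'} p(x→x') τ(x')` elsewhere. The
state space has `N^N` elements, so the full solver
(`absorption_time_full`) is capped at `N ≤ 5` and serves mainly as an
independent oracle.

Because neutral type labels are exchangeable, only the *partition* of
vertices by shared type matters: the state `Ω` is a set partition of `V`,
and the event `(u, v)` moves `v` into `u`'s block (dropping the emptied
block if `v` was a singleton). This lumped chain (`absorption_time_lumped`)
has Bell-number size — `B(8) = 4140` instead of `8^8 ≈ 1.7×10^7` — and is
exact, not approximate; the suite verifies full-vs-lumped equality on every
connected graph with `N ≤ 4` and on random strongly connected digraphs,
both rules, to `1e-9` relative tolerance.

Partitions are canonicalized as restricted-growth strings (first block
label 1, each new block taking the next integer) and indexed in
lexicographic order, so state numbering is reproducible across runs. The
sparse transient system `(I − Q) τ = 1` is solved in double precision with
`Matrix::solve`. Double precision is sufficient for every tolerance the
package promises (`1e-9` relative on desk-scale chains whose entries are
rationals with small denominators); we deliberately do not carry an
arbitrary-precision rational mode, trading bit-exact regression values for
a dependency-free solver.

Practical capacities, chosen so every routine finishes in seconds to
minutes on one core: lumped solver `N ≤ 10` (`B(10) = 115 975`), full
solver `N ≤ 5`, fixation subset chain `N ≤ 14`. Exceeding them raises a
capacity error that names the alternative (lumped solver or simulation)
rather than attempting the computation.

### Closed forms

For the well-mixed population (complete graph with self-loops) the time
from an abundance configuration `λ = (λ1 ≥ … ≥ λk)`, `Σλi = N`, has two
equivalent forms: a double sum over types and ranks, and a histogram form
`T = N (N − Σ_{h=0}^{N−1} b_h/(N−h))` built from the profile
`b_h = Σ_i max(λi − h, 0)`. `complete_time()` evaluates **both** and stops
unless they agree to `1e-9` relative — the identity across every partition
of every `N ≤ 12` is part of the test suite. From maximal diversity the
value is `N(N−1)`; without self-loops, `(N−1)²`.

For the cycle, types started from maximal diversity always form contiguous
arcs, and `cycle_time()` returns `(N+1)N(N−1)/6 − Σ_h b_h·h`. Contiguity is
a *precondition the caller owns*: the formula depends only on `λ` given
contiguity, and the function cannot check arrangement from `λ` alone. The
suite cross-checks it against the lumped solver on clustered partitions.

The star formula `T = n³ − n² + nH_n` (hub plus `n` leaves, bd updating) is
a *conjecture* and is flagged as such in its result object. The lumped
solver confirms it exactly for `n = 2..5`; the tests are written so a
violation at any checked `n` surfaces as a failure rather than being
absorbed into a tolerance. The conjecture is never used as ground truth for
any other check.

### Fixation probabilities

`fixation_probability(g, rule, focal)` pools all non-focal types into one —
exact under neutrality — and solves the first-step system on the `2^N`
chain of occupied subsets, with `φ(∅) = 0`, `φ(V) = 1`. Neutral-drift
symmetry (`1/N` per singleton on vertex-transitive graphs) and the
sum-to-one property over all singletons are tested, as is the star-hub
value `1/(1+n²)`.

## Simulation

The Monte-Carlo engine is compiled (Rcpp). Each replicate `r` of a run with
user seed `s` draws from a private xoshiro256++ stream seeded by
splitmix64 mixing of `(s, r)`: replicates are reproducible individually,
independent of execution order, and independent of R's global RNG (which
the R-level `step_once()` uses instead, so `set.seed()` governs the
one-step audits). Runs hitting `max_steps` (default `1e9`) return an
explicit censoring flag; means are never computed over silently truncated
replicates.

Characteristic curves record the number of distinct types at requested
time points, freezing the count once absorbed; grids default to log-spaced
points because absorption dynamics span decades. Curve runs stop at the
last requested time point rather than at absorption.

Calibration checks in the suite: sample means within 3 standard errors of
the exact values for the complete graph (`56` at `N = 8`), cycle (`165` at
`N = 10`) and star (`N = 6`, bd, against the lumped solver); one-step event
frequencies within binomial `4σ` of the rule probabilities at `N ≤ 4`;
bd/db distributional agreement on the cycle (`N = 8`) by a two-sample test;
uniform winner distribution on vertex-transitive graphs.

## Enumeration

`enumerate_connected_graphs(N)` generates one representative per
isomorphism class of connected undirected simple graphs by vertex
augmentation: every representative on `N − 1` vertices is extended by a new
vertex joined to each nonempty subset of the old ones, and candidates are
deduplicated by canonical code (igraph's BLISS canonical permutation,
serialized as graph6). Every connected graph contains a non-cut vertex
whose removal leaves a connected graph, so the scheme is exhaustive.
Filtering all `2^{28}` edge subsets at `N = 8` would be infeasible;
augmentation touches about `10^5` candidates and finishes in well under a
minute, reproducing the census 1, 1, 2, 6, 21, 112, 853, 11117 for
`N = 1..8` (brute-force edge-subset enumeration corroborates `N ≤ 5` in the
tests). Capacity is capped at `N = 8`, the largest size the package's
analyses use.

Graph edit distance is restricted to equal-order graphs — the minimum over
vertex bijections of the edge-set symmetric difference, by pruned brute
force over permutations. All its uses here compare graphs of one fixed
size; the vertex-insertion branch of the general definition is out of
scope.

## Comparative analyses

`sweep_exact(N)` runs the lumped solver from maximal diversity over every
enumerated graph and tabulates bd time, db time, their ratio, and the
normalized degree entropy
`−(1/log N) Σ_u p(u) log p(u)`, `p(u) = deg(u)/Σ_v deg(v)`, which is 1
exactly for regular graphs and minimized by the star. Headline exhaustive
comparisons run at `N ≤ 6` (143 connected graphs across `N = 1..6`,
`B(6) = 203` lumped states — seconds); the suite verifies there that db
never exceeds bd, with equality exactly on regular graphs, that the double
star is the slowest bd absorber, and that adding an edge can raise and then
lower the bd time. The corresponding `N = 8` sweep (11,117 graphs × 4140
states) is reachable through the same functions as a long-running job but
is deliberately not a test.

`scaling_slope()` fits least squares to `log T` vs `log N`. At desk sizes
the slope carries subleading corrections — for the complete family the
closed form `N(N−1)` itself pins the `N = 4..8` slope at `2.2218`, not 2 —
so trend checks assert agreement with the closed-form oracle where one
exists and otherwise membership in wide windows (star bd in `[2.5, 3.3]` at
`N ∈ {25, 50, 100}`; double star bd in `[3.3, 4.7]` at `N ∈ {10, 20, 30}`;
star db times within a factor 1.5 of proportionality to `N log N`), never
convergence to the asymptotic exponent.

The directed contracting star (bidirectional-path blades around a hub plus
one-way inward edges between every farther/closer pair on a blade) is the
package's superexponential structure. Blades shorter than 3 admit no
contracting edges — `N = 5, b = 2` degenerates to the undirected path — so
the strict path-vs-contracting comparison is run at `N = 9`, where the
effect is unambiguous at `α = 0.01` with 100 replicates. A design note: the
construction keeps contracting edges strictly within blades; the hub
receives only the bidirectional links from each innermost blade vertex.
This is the reading most consistent with the family's published figures,
and it is the only point where the construction is genuinely ambiguous.

## Design decisions and limitations

* **Double star with odd `N`**: the extra leaf goes on the first hub,
  deterministically.
* **Barbell**: each path endpoint attaches to exactly one clique vertex
  (path endpoints have degree 2, clique attachment vertices degree `n`) —
  forced by the invasion-probability reasoning for the family.
* **Pareto front**: records maximal in `(bd, db)` — kept iff no other
  record is at least as large in both coordinates and larger in one;
  deterministic order by bd time.
* **Simulation problem sizes** used by the suite (250–1000 replicates at
  `N ≤ 100` for calibration and slopes; 100 replicates for the contracting
  comparison) were chosen as the smallest runs whose standard errors make
  the qualitative orderings unambiguous; all finish in seconds thanks to
  the compiled engine.
* The synthetic study conditions are exactly the model's: maximal-diversity
  starts, neutral types, no mutation, unweighted graphs. Passing tests
  certify the mathematics of this idealized process, not the behavior of
  real populations — no fitness differences, no mutation-drift balance, no
  weighted or dynamic interaction structure. The diversity measure is the
  count of distinct types; frequency-aware indices (Simpson, Shannon) are
  out of scope.
* Exact solvers assume strong connectivity (absorption is otherwise not
  guaranteed from every state); predicates are checked via igraph and a
  singular lumped system is reported as a structural error rather than
  patched.
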