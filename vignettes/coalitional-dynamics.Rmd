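---
title: "Coalitional better-response dynamics on networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalitional better-response dynamics on networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalnet)
```

## The model

`coalnet` simulates a population of `n` individuals on a fixed,
undirected interaction graph. The graph is drawn once, before the
dynamics start, and never changes. Each individual plays one of two
strategies, Cooperate or Defect, and receives the sum over its
neighbors of the pairwise prisoner's dilemma payoffs

\[ u(C,C) = 2b - c, \quad u(C,D) = b - c, \quad u(D,C) = b, \quad u(D,D) = 0, \]

with \(2b > c > b > 0\): cooperation is a public good worth \(b\) to each
party at private cost \(c\). Payoffs are *flows* — they are recomputed
from the current strategy profile whenever they are needed and never
accumulate across periods. This matters because the update rule compares
an individual's current payoff with its payoff after a hypothetical
joint switch, holding everyone outside the coalition fixed; a stateless
evaluation is the only reading under which that comparison is coherent.

Each period \(t = 1, \dots, T\) exactly one coalition updates:

1. **Size.** \(k = 1 + X\) with \(X \sim \mathrm{Binomial}(\bar k - 1, p)\),
   \(\bar k = 5\). The trial count \(\bar k - 1\) is the unique binomial
   for which the support of \(k\) is exactly \(\{1, \dots, \bar k\}\);
   \(p = 0\) recovers classical individualistic better-response dynamics
   and \(p = 1\) always selects maximal coalitions.
2. **Membership.** A coalition of size \(k\) must induce a connected
   subgraph (main treatment) or a clique (robustness treatment). We draw
   *uniformly* from the exhaustively enumerated feasible sets of size
   \(k\). Uniformity is a modelling choice — the least arbitrary one
   given that membership is simply "randomly selected"; growth or
   random-walk samplers were rejected because they bias towards
   high-degree vertices in ways that are hard to characterize.
3. **Decision.** The coalition evaluates the two uniform joint switches —
   every member to Cooperate, every member to Defect — holding
   non-members fixed. If exactly one of them gives every member at least
   its current payoff, it is applied. If both do, each outcome occurs
   with probability one half. If neither does, strategies are unchanged.

Under this rule every member of an updating coalition ends the period
with a weakly higher payoff than it started with (given non-members'
strategies); the engine can assert this invariant after every update
(`validate = TRUE` in `simulation_config()`).

## Tie-breaking semantics

Two corner cases of step 3 deserve explicit statement, because they are
what make the long-run behavior clean:

* **The status quo counts.** For a coalition whose members all play
  Defect, the all-to-Defect "switch" is the status quo and trivially
  gives every member at least its current payoff. Hence when the
  all-to-Cooperate switch profits every member, *both* options hold, and
  the coalition moves to Cooperate with probability one half. This is
  the engine of cooperation: isolated dense clusters of defectors
  escape the all-Defect state by coin flip, not by strict-dominance
  reasoning. Symmetrically, a lone cooperator with neighbors (for whom
  defecting is a strict improvement but staying put is weakly fine)
  defects with probability one half per update — cooperation decays
  rather than vanishing in one sweep.

* **Complete indifference resolves to Defect.** If no member's payoff
  differs across staying, all-Cooperate and all-Defect — the prototype
  is an isolated vertex updating alone, whose payoff is 0 whatever it
  plays — the coalition adopts Defect, the weakly dominant strategy,
  instead of randomizing. A coin flip here would make isolated vertices
  flicker between strategies forever, and sparse random graphs at
  `e = 0.05` almost always contain isolated vertices; the flicker would
  put a floor of roughly half the isolated-vertex count under the
  cooperation share even at `p = 0`, where cooperation should be — and,
  with this tie-break, is — exactly zero in the long run. We regard
  "indifferent agents do not spontaneously adopt a weakly dominated
  action" as the natural refinement, and it is the minimal one that
  makes the all-Defect state absorbing under individualistic updating
  on every graph.

```{r tiebreak}
M <- pd_matrix_from_benefit_cost(3, 4)
g <- interaction_graph(3, rbind(c(2, 3)))      # vertex 1 is isolated
apply_coalitional_better_response(g, M, c(1L, 0L, 0L), S = 1)[1]  # -> Defect
```

## The defector's gain, in closed form

For a member currently playing Defect, with degree \(d\) and \(s\)
neighbors switching to Cooperate alongside it, the payoff change of the
all-to-Cooperate switch is exactly \((b - c)d + b\,s\): every
non-switching neighbor contributes \(b - c\) regardless of its strategy,
and every co-switching defector adds \(b\). The switch is weakly
profitable iff \(s/d \ge (c - b)/b\) — the member's *share of neighbors
inside the coalition* is what matters. This single inequality explains
the two headline comparative statics: larger \(p\) means larger
coalitions (larger \(s\)), and lower edge density means smaller \(d\)
for given \(s\). It also pins down two boundary regimes: at \(c = 2b\)
a defector switches only if *all* of its neighbors will play Cooperate
(\(s = d\)), and for \(c \le b\,n/(n-1)\) a defector always switches
when at least one neighbor comes along (\(s \ge 1\) suffices, since
\(d \le n - 1\)). The package exposes the formula as
`defector_gain_closed_form()`, and the test suite verifies it
exhaustively against brute-force payoff differencing on small graphs —
it is an independent oracle for the engine, not part of it.

## Graph generation

* **Erdős–Rényi at exact density.** Edge density is defined as the ratio
  of realized to possible edges, so we use the fixed-edge-count
  \(G(n, m)\) model with \(m = \mathrm{round}(e \cdot n(n-1)/2)\): the
  realized density equals the target up to edge-count rounding, for
  every seed. The binomial \(G(n, p)\) variant would add between-graph
  variance in density itself, confounding the density axis of the
  sweeps.
* **No connectivity conditioning.** Sparse graphs are frequently
  disconnected, with isolated vertices; that is part of the studied
  regime (coalitions never span components, and sizes with no feasible
  coalition are handled below), so we do not reject disconnected draws.
* **Watts–Strogatz.** A ring lattice of even degree \(k\) with each edge
  rewired independently with probability \(\beta\), avoiding self-loops
  and duplicates so the edge count \(nk/2\) is conserved exactly. To
  match a target density the lattice degree is the nearest even integer
  to \(e(n-1)\); the realized density \(k/(n-1)\) is stored next to the
  target in the `graph_spec`.

## Coalition enumeration and infeasible sizes

Feasible coalitions are enumerated exhaustively (connected sets by an
ESU-style extension algorithm, cliques by ordered extension, both in
C++) and cached per graph and size — for the benchmark `n = 32`,
`k ≤ 5` there are at most \(\binom{32}{5} = 201{,}376\) candidate sets,
well within exact reach, so no approximate sampler is needed. A guard
rejects exhaustive enumeration for populations beyond a few hundred
vertices.

On sparse graphs some sizes may admit no feasible coalition at all (all
components smaller than \(k\)). The size distribution is then restricted
to the feasible sizes and renormalized; size 1 is always feasible, so
this is well defined except in one degenerate corner: if the restricted
support carries zero probability (e.g. \(p = 1\), which puts all mass on
size 5, on a graph whose components all have fewer than 5 vertices), the
largest feasible size is used. Internally both engines draw the size by
single-uniform inversion of this restricted distribution, which is
distributionally identical to redrawing from the binomial until a
feasible size appears but costs bounded work per period.

## Experiments

* `run_simulation()` — one trajectory; records the cooperation share
  after every update and each vertex's cooperation frequency over the
  measurement window.
* `sweep_grid()` — the contour-map design: for each \((p, e)\) cell,
  fresh random graph *and* fresh half-random profile per replicate, cell
  value = mean of the per-replicate window means, per-replicate values
  retained.
* Collaboration schedules — a time-indexed override of \(p\) (phases
  must partition \([1, T]\)), used for the off/on "catastrophe" design
  in which cooperation collapses during a `p = 0` phase and recovers
  after restart.

Default problem sizes follow the study conditions: `n = 32`,
`T = 3000` updates with measurement window 2501–3000 for sweeps (the
sweep experiments use 50 graphs per cell), and `T = 10000` with window
9501–10000 is the intended configuration for per-node maps (all
configurable). The acceptance script and tests run the sweep designs at
these sizes; the 5×5 monotonicity grid uses \(p \in \{0, 0.25, 0.5,
0.75, 1\}\), \(e \in \{0.05, 0.1, 0.2, 0.3, 0.4\}\), our choice since
only the qualitative surface, not a printed grid, is available to match.

**Seeding.** All randomness flows from a single seed. Sweeps derive one
child seed per replicate from the master seed, so any cell or replicate
can be reproduced in isolation; the CLI writes every seed into the run
manifest. The C++ engine uses R's own RNG and consumes draws in a
documented order (size, membership index, optional tie coin), and a
pure-R reference engine reproduces its trajectories *exactly*, draw for
draw — the equality is asserted in the test suite, so the compiled hot
path is checked against readable R code rather than trusted.

## Numerical choices

Payoff comparisons are exact (`>=` on doubles) when all four matrix
entries are integers, which covers every benchmark treatment; integer
sums are exactly representable, so no tolerance is appropriate. For
non-integer matrices an absolute tolerance of \(10^{-9}\) is applied to
the weak-improvement and indifference comparisons. Degenerate inputs are
rejected loudly rather than guessed at: `T = 0` runs, half-random
initialization with odd `n`, measurement windows outside \([1, T]\),
schedules with gaps or overlaps, and payoff pairs violating
\(2b > c > b > 0\) (the error names the failed inequality).

## What the generated data do and do not show

The generators emulate the study conditions exactly: random interaction
structure at controlled density, equal initial shares of the two
strategies, and payoffs in the public-goods parameterization. They do
not emulate features of real social networks — degree heterogeneity
beyond the binomial, clustering/community structure (except via the
Watts–Strogatz treatment), dynamic tie formation — nor noise in
decision-making (all updates are exact better responses). Passing tests
therefore validate the model's internal logic and its comparative
statics on random graphs; they are not evidence about empirical social
networks.

## Known limitations

* Exhaustive enumeration limits population size (guarded); very large
  populations would need an approximate uniform sampler with its own
  bias analysis.
* Only the two uniform joint switches are evaluated, exactly as the
  update rule specifies; coalitions never consider mixed deviations, so
  "better response" is coalition-uniform by construction.
* No imitation, mutation, birth–death or evolving-\(p\) dynamics; the
  collaboration parameter is exogenous and common to the population.
* Per-node maps on non-default windows require recording the full
  strategy history (`record_profiles = TRUE`), which costs \(T \times n\)
  integers of memory.
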