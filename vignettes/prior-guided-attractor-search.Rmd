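---
title: "Prior-guided attractor search in synchronous Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-guided attractor search in synchronous Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attapriori)
```

## The model and its assumptions

A synchronous Boolean network assigns each node $x_i \in \{0,1\}$ an update
function $f_i$ over its input set, and updates all nodes simultaneously:
$\mathbf{x}(t+1) = \mathbf{f}(\mathbf{x}(t))$.  Determinism and a finite
state space force every trajectory into an attractor — a fixed point or a
cycle of period $t_p > 1$ whose states repeat forever.  The package commits
to synchronous semantics throughout: asynchronous schemes produce
non-unique trajectories, and for bipartite models (where a reaction must
consume its source state and produce its product state in the same tick)
they can silently delete components, so they are out of scope by design.

Attractors are what biological Boolean models are interpreted through, but
locating a particular one is expensive: the state space has $2^n$ states
and no sub-$O(2^n)$ algorithm is known for periodic attractors of period
$\ge 3$ in general networks.  The approach taken here is heuristic in the
choice of *where to look first*, yet exhaustive in the limit: given a guess
bit $b_i$ and a confidence $p_i \in [0.5, 1]$ per node, start vectors are
enumerated from the most plausible outward, and each is simulated to its
attractor.  If the prior carries real information ($p > 0.5$) the expected
work until the target region is reached drops exponentially below $2^n$;
if the prior is vacuous the search degrades gracefully to full enumeration.

## The enumeration order

Priors are canonicalized first: a node guessed 1 with probability 0.3 is
re-expressed as guessed 0 with probability 0.7, so all confidences end up
in $[0.5, 1]$.  Three kinds of bits result:

* **fixed** ($p_i = 1$): never flipped; a start vector conflicting with a
  fixed bit is never examined (and `trial_index_of_target` reports such
  targets as unreachable rather than silently mis-ranking them);
* **informed** ($0.5 < p_i < 1$): flipped, rarely;
* **uninformed** ($p_i = 0.5$): carry no ordering information at all.

With a single informed class the order is: Hamming distance $k$ from the
guess first, and within a weight class increasing numeric value of the
flip pattern, with $x_n$ as the least-significant bit (for $n = 3$ and
guess 000: 000, 001, 010, 100, 011, 101, 110, 111).  Ties within a weight
class are theoretically arbitrary — every such order has the same expected
trial count, because the within-class rank of a uniformly random flip set
is uniform — but fixing the numeric tie-break makes trial indices exactly
computable: the vector with flip significances $c_1 < \dots < c_k$ sits at

$$I = S(n,k) + 1 + \sum_{j=1}^{k} \binom{c_j}{j},$$

the prefix count of lighter vectors plus the colexicographic rank of the
flip set.  `rank_start_vector`/`unrank_start_vector` implement this in
$O(n)$ arithmetic, which is what lets the trial-count benchmark average
indices around $10^{10}$ without enumerating anything.

With several informed classes (the implementation supports any number; the
historical C implementation capped it at three) the package enumerates
per-class flip-count tuples $(k_1, \dots, k_h)$ in nondecreasing total
log-odds cost $\sum_c k_c \ln\!\frac{p_c}{1-p_c}$, ties broken by fewer
total flips and then lexicographically; within a tuple the per-class flip
sets form a Cartesian product with higher-confidence classes varying more
slowly.  This generalizes the single-class order (to which it reduces
exactly) and respects per-class flip thresholds.  No published reference
pins the multi-class order beyond "higher probabilities first", so this is
a documented package choice, and all theory-level tests avoid depending on
within-class tie order.

Uninformed bits are enumerated innermost: for each informed pattern, all
$2^{n_2}$ assignments appear in a pseudo-random order.  The order is a
seeded bijection (a bit-position permutation composed with an XOR mask,
derived from the seed and the informed-pattern index by a small dedicated
LCG) rather than a materialized random permutation: it is complete,
reproducible, needs $O(n_2)$ memory, and never touches R's global RNG.
The trade-off is that it is "only" pseudo-random — adjacent patterns are
correlated in a way a true shuffle would not be — which is irrelevant
here, since the semi-informed complexity analysis requires completeness
and symmetry of the uninformed block, not cryptographic randomness.

## Trajectory simulation and attractor identity

`simulate_to_attractor` walks $\mathbf{x}(0), \mathbf{x}(1), \dots$ keeping
a hash from visited state to time index, so the first repeat and its entry
position $t'$ are found in one pass; the attractor is the suffix from $t'$
and the transient length is $t'$ (the cycle itself is excluded, the
convention used by all trajectory-length statistics here).  Memory is
proportional to trajectory length, not $2^n$; trials are independent by
default (no cross-trial memoization) because the expected-trials analysis
treats them so, and memoization would trade a theory-conformant $O(L)$
memory footprint for a worst-case $O(2^n)$ one.

Every trajectory is capped (default `step_cap = 100 n`, configurable).
Trajectories of practically relevant networks are short — the benchmark
below measures means around 100–200 steps at $n = 100$ — but a cap is
needed for the complexity statement to hold for adversarial networks; a
capped trial counts as failed.  The cap bounds detectable periods and
transients, so results on networks suspected of exponentially long cycles
should raise it explicitly.

Attractors are canonicalized by rotating the cycle to start at its
numerically smallest state ($x_n$ least significant), making identity
phase-independent; deduplication, censuses and the guided-vs-random
comparison all key on this canonical form.  `enumerate_all_attractors`
(default limit $n \le 20$) walks every state with memoized basin
assignment and serves as the oracle the search is tested against.

## Closed-form expectations and envelopes

`expected_trials(n, p)` evaluates $E(n,p)$ with the inner sum over the
within-class rank collapsed in closed form.  For $n \le 500$ the sum is
taken directly in doubles — every intermediate is an exact integer below
$2^{53}$ for the $n \le 40$ uses, and stays inside double range up to
$n = 500$ — and beyond that in log domain via `lchoose` and log-sum-exp.
No arbitrary-precision arithmetic is used anywhere; the worked small-case
values (5/4, 7/4, 5/2) are binary-exact doubles, which is what the exact
tests assert.

`complexity_base(p)` returns $\alpha^*$, $\beta$ and $f(\alpha^*)$, both
raw and rounded to three decimals (the reporting precision for bases;
ratios are reported at 3–5 significant figures).  `theoretical_trial_bound`
exposes the envelope $f(\alpha^*)^n n^2$ with its unspecified constant
fixed at 1 and documented as an envelope, not an expectation — on the
tested range $n \le 40$, $E(n,p)$ lies below it with constant 1 already.
`naive_ratio` defaults to the literal printed base 1.917 rather than the
unrounded $f(\alpha^*)$, because the published comparison numbers are
quoted on that scale.  `semi_informed_bound` multiplies the envelope by
$2^{n_2}$ for $n_2$ uninformed bits.

## The synthetic benchmark generators

`generate_nk(n, k, seed)` draws, per node, $k$ distinct inputs uniformly
(self-inputs allowed by default, mirroring the usual random-topology
convention; a flag disallows them) and an independent uniformly random
truth table over the $2^k$ rows, realized as an OR of full minterms so the
expression references exactly its declared inputs.  Constant tables
(all-0/all-1) are resampled: a constant rule would make the realized
indegree 0 and break the structural "exactly $K$ inputs" contract.  The
resampling is 0/1-symmetric, so table entries remain fair coins — the
uniformity test conditions on this.  `perturb_state` flips each bit with
probability $1-p$; `random_state` draws fair coins; `mutate_functions`
relabels each AND (or OR) operator node independently with the given rate,
touching nothing else.  All generators are pure functions of their seed
and restore the caller's RNG state; harnesses derive per-replicate seeds
from one master seed by fixed labeled offsets.

What these emulate — and what they do not: random N-K networks with
$K = 2$ sit at the critical connectivity regime and are the standard
yardstick for attractor algorithms, but they lack the modularity, biased
truth tables and long-tailed indegree distributions of curated biological
models.  Passing benchmarks on them validates ordering, counting and
scaling behavior; it does not certify performance on any particular
biological network, which is why the loaders accept user-supplied models
in the same dialect.

## Benchmark protocols and problem sizes

Three harnesses reproduce the standard evaluation protocol; the problem
sizes below are the package's defaults, chosen to keep a full run in
minutes on one core while matching the published conditions where they
matter:

* `run_trials_experiment` — per (N, p): one seeded network, a target
  attractor state found by simulating from a random start, then 1000
  replicates of "perturb the target at retention $p$, compute the closed-
  form trial index of the target".  Counting ranks instead of running
  trajectories is mathematically identical to the target-equality stopping
  rule, whose expectation is exactly $E(n, p)$ — the analytic column the
  harness reports next to the simulated mean.  At $N = 40$, $p = 0.7$ the
  mean sits near $3.6\times10^{10}$; note the distribution is heavily
  right-skewed (exact SD $8.1\times10^{10}$ at $p=0.7$ and $2.8\times10^8$
  against a mean of $1.4\times10^7$ at $p=0.9$), so 1000-replicate means at
  high $p$ scatter by tens of percent and only the order of magnitude, or
  agreement with $E(n,p)$ within Monte-Carlo error, is meaningful.
* `run_trajectory_length_experiment` — per size: fresh seeded networks
  and random starts, transient lengths (cycle excluded) and periods
  averaged separately; capped replicates are excluded and counted.  At
  $N = 100$, $K = 2$, 100 replicates the mean transient is well below 300.
* `run_comparison_experiment` — per network: a fixed canonical target;
  the guided method restarts along the prior stream from a perturbed
  guess ($p = 0.9$), the random method from uniform states, both summing
  transient steps until the target attractor is hit.  Both methods
  verifiably reach the same canonical attractor; runs hitting the restart
  cap are excluded and flagged.  The test suite asserts the inequality
  direction (guided $\le$ random within a 3-SE margin) rather than a
  specific speedup factor, which is configuration-dependent.

`run_scenario_sweep` drives the biological protocol: fixed nodes at
confidence 1, remaining nodes filled all-ON or all-OFF as the guess with a
swept confidence, collect-all search under trial/time limits, one output
row per detected attractor.

## Annotation rules

`classify_behavior` matches partial marker signatures and requires
stability: the signature must hold in *every* cycle state, so an attractor
whose marker oscillates is atypical even if some states match.  A variant
accepting "holds in some state" exists behind `match = "sometimes"` but is
not the default, because a non-stable signature does not correspond to a
fixed cell behavior.  Schemes whose signatures both match one concrete
attractor raise a configuration error rather than picking silently.

`check_validity` enforces exactly-one-true per mutually exclusive stage
group in every cycle state, plus optional required components (at least
one representing node true throughout).  `call_viability` marks a valid
attractor viable iff it is periodic and every stage of every group is
visited somewhere in the cycle; point attractors are lethal by definition.
`absent_components` compares an attractor against a reference: a component
whose every representing node is constitutively 0 while active somewhere
in the reference is a de-facto deletion mutant; constitutively-zero nodes
outside the component map are listed as a residue for manual review.  The
stage-group and component tables are model-specific user configs (TSV);
the package bundles only constructed toy fixtures exercising every rule.

## Numerical and degenerate-input choices

* Trial indices, prefix counts and expectations are doubles: exact below
  $2^{53}$, log-domain beyond; no bignum dependency.
* State identity uses bit-string keys, valid for any $n$; the integer
  view of a state is provided only for $n \le 52$.
* $p = 0.5$ is accepted by `expected_trials` (the uninformed-order limit,
  $E = (2^n+1)/2$) and by the iterator (uninformed bits); the envelope
  functions require $p > 0.5$ since $f = 2$ carries no information.
* `0^0 = 1` convention at $p = 1$: the guess is examined first, $E = 1$.
* Time limits are checked between trials only, so a single pathological
  trajectory can overshoot the limit by its own duration; trial limits
  are exact.
* Empty marker schemes, empty groups and empty component maps are valid
  and yield "atypical"/valid/no-calls respectively.

## Known limitations

* No asynchronous or probabilistic semantics, by design.
* The search guarantees nothing about attractors whose every state is far
  from the guess when trial/time limits are set; that is the price of a
  heuristic order and the reason collect-all mode reports its termination
  reason.
* Enumerating *all* attractors via the stream costs $\ge 2^n$ trials and
  is only sensible for small $n$; the package refuses brute-force
  enumeration above a configurable limit instead of attempting it.
* Expression evaluation compiles truth-table lookups only for indegree
  $\le 12$; wider rules fall back to tree evaluation to keep per-step cost
  proportional to expression size.
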