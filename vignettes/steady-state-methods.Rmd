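---
title: "Computing steady states of Boolean networks: model, method, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing steady states of Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnsteady)
```

## The model and the problem

A Boolean network on variables $x_1,\dots,x_n$ over $\{0,1\}$ assigns each
variable an update function $f_i:\{0,1\}^n\to\{0,1\}$; the synchronous map
$f=(f_1,\dots,f_n)$ defines the dynamics. `bnsteady` computes the set of
**steady states** $\{x : f(x)=x\}$ exactly — no sampling, no heuristics. It
deliberately does *not* compute limit cycles of period greater than one,
asynchronous dynamics, or attractor basins; multi-valued (non-Boolean)
logical models are also out of scope.

Steady-state determination is NP-hard in general, so the package bets on
the structure of real molecular networks: sparsity (mean in-degree around
2–3) and large "frozen" components. The pipeline combines two reductions
that each preserve the steady-state set bijectively, and a final exact
algebraic solve on whatever small core remains.

## Stage 1: the AND-NOT transform

Every update rule is first constant-folded, XOR-expanded
($a \oplus b \to (a\wedge\neg b)\vee(\neg a\wedge b)$), and put in negation
normal form. The structural rewrite then maps each rule to a conjunction of
signed literals, introducing an auxiliary variable for every OR (by
De Morgan, $e_1\vee e_2 = \neg(\neg e_1 \wedge \neg e_2)$) and for every
non-literal conjunct. Auxiliaries are appended after the original
variables, so projection onto the first $n$ coordinates is a bijection
between the steady states of the AND-NOT network $g$ and those of $f$. The
conversion is structural rather than DNF-based: `!x2 & (x3 | x4)` costs one
auxiliary, not three, and there is no exponential blow-up. No logic
minimization beyond constant folding is attempted at this stage.

One numerical consideration shapes the transform: the square-free GF(2)
polynomial of a conjunction of $w$ negated literals has $2^w$ monomials.
Conjunctions wider than `max_width = 6` are therefore chunked into
sub-auxiliaries, which bounds every polynomial later handed to the algebra
stage at $2^6+1$ monomials while adding only $O(w/6)$ variables per wide
rule. Without this cap a single 15-literal rule produces a 32 769-monomial
polynomial that stalls the Gröbner computation.

## Stage 2: wiring-diagram reduction

The signed wiring diagram of $g$ (edge $x\to y$ with sign $+$/$-$ per
literal) is reduced to a fixpoint of four motif rules, each with an
elementary steady-state-preservation argument:

* **R1 constant propagation** — a node with constant function is
  substituted into its targets and removed (a satisfied literal is
  dropped; an unsatisfied one forces the target to constant 0).
* **R2 unit-input elimination** — a node $y$ whose conjunction is a single
  literal of another node $x$ satisfies $y=\pm x$ *exactly* at any fixed
  point, so every occurrence of $y$ is replaced by the sign-composed
  literal of $x$ and $y$ is removed. Sign collisions normalize the target
  to constant 0.
* **R3 sink elimination** — a node with out-degree 0 and no self-loop
  constrains nothing; its value is determined by its conjunction and is
  reconstructed during backtracking.
* **R4 feed-forward redundancy** — with edges $x\to y$ (sign $s$),
  $y\to z$ ($+$), $x\to z$ ($s$), the direct $x$-literal in $z$ is
  redundant: $y=1$ at a fixed point already forces it, and $y=0$ forces
  $z=0$ regardless. Only the edge is deleted.

Rules apply in the order R1 (to exhaustion), R2, R4, R3, rescanning after
any change, with declaration-order tie-breaks, so traces are reproducible.
Each application removes a node or an edge, which bounds the loop. Nodes
with self-loops are never removed (except via R1 once constant): positive
self-loop inputs (`x = x`) carry the environment's degrees of freedom and
must survive to the solver, and negative self-loops (`x = !x`-like
constraints) are left for the algebra stage rather than handled by a
special rule — correctness over aggressiveness.

Every removal is recorded (constant value, alias literal, or sink
conjunction); replaying the trace in reverse lifts any steady state of the
reduced network $h$ to one of $g$, and each lifted state is re-checked with
`is_steady_state()` so a rule bug would surface as a loud
internal-consistency error, never a silently wrong answer.

On sparse random networks this stage is dramatic: a 1000-node $K=2$
Kauffman network typically transforms to $m \approx 1500$ and reduces to a
core of 10–60 nodes.

## Stage 3: polynomial solving over GF(2)

Boolean functions correspond uniquely to square-free polynomials over the
two-element field via $x\wedge y \leftrightarrow xy$,
$x\vee y \leftrightarrow x+y+xy$, $\neg x \leftrightarrow x+1$. The fixed
points of $h$ are the common zeros of $p_i = h_i + x_i$. All arithmetic
happens in the Boolean quotient ring (exponents truncated to 1,
coefficients mod 2), so the field relations $x^2=x$ are built in rather
than carried as extra generators — bases stay small and termination is
guaranteed in a finite ring.

The solver computes a reduced lexicographic Gröbner basis with Buchberger's
algorithm (compiled code; monomials are sorted integer vectors). Two
details matter:

* **Field-relation S-polynomials.** Working in the quotient ring requires,
  for each basis element $f = m + r$ and each variable $x \mid m$, the
  S-polynomial against $x^2+x$, which simplifies to $x\cdot r + m$.
  Omitting these yields non-bases. For the same reason Buchberger's
  coprimality (product) criterion is *not* applied — it is invalid in the
  quotient ring — and pair selection uses the normal strategy (smallest
  lcm first).
* **Elimination order.** The order is feedback-guided: a greedy feedback
  vertex set of $h$'s wiring diagram is placed lowest and the acyclic
  remainder in reverse topological order. Every non-feedback equation then
  has the *linear* leading term $x_i$, so the lex basis computation is
  essentially the triangular "generalized Gaussian elimination" it is
  meant to enable; only the few feedback variables carry nonlinear leading
  terms. An occurrence-count heuristic is the fallback for hand-built
  systems. The solution set is provably independent of the order, and a
  property test checks invariance under two different orderings.

Solutions are enumerated per connected component (equations linked by
shared variables), branching from the lowest variable of the elimination
order upward, pruning any branch whose partially substituted basis contains
1; component solutions combine as a Cartesian product, and variables
appearing in no equation (environmental inputs) contribute a free factor of
2. A configurable solution cap (default $10^5$) converts combinatorial
explosion — e.g. dozens of free inputs — into a distinct
`bnsteady_cap_error` rather than an unbounded enumeration, and an optional
wall-clock timeout (`solve_network(..., timeout =)`) makes dense
intractable models fail loudly instead of hanging.

## Verification oracles

Two independent methods check the pipeline, mirroring the validation design
of testing an implementation against a differently-derived oracle:

* `enumerate_exhaustive()` scans all $2^n$ states (refused above a cap,
  default $n\le 22$).
* `enumerate_via_fvs()` fixes the coordinates of a feedback vertex set
  $S$ of the dependency graph; the acyclic remainder is then determined in
  topological order, giving $2^{|S|}$ candidates that are filtered by
  $f(x)=x$. `find_fvs()` computes an exact minimum FVS by branch and bound
  over shortest cycles up to 25 nodes and a greedy heuristic above
  (self-loops first, then the vertex on the most shortest cycles); only
  *validity* (acyclicity after deletion) is load-bearing for correctness,
  minimality is an optimization, so the NP-hardness of minimum FVS never
  threatens the oracle.

`solve_network()` additionally re-verifies every emitted state against the
original network before returning, for every method.

## Random network generators

The benchmark classes are seeded and fully reproducible (byte-identical
rule files from equal seeds; the caller's RNG state is untouched).

* **Kauffman N-K**: every node draws exactly $K$ distinct regulators
  uniformly (self-regulation allowed by default, `allow_self = FALSE` to
  forbid) and a uniformly random truth table on its $2^K$ input
  combinations. Tables are rendered as a minimal two-level expression
  (prime implicants with a greedy cover, or the complemented form when
  cheaper); a sampled table that does not depend on one of its inputs
  therefore yields a rule that does not mention it, and a constant table
  yields `x = 0/1`. The *drawn* regulator sets are preserved in
  `attr(net, "regulators")`, which is what the structural contracts
  (constant in-degree $K$) are stated about.
* **Power-law in-degree**: in-degrees are sampled from
  $P(k)\propto k^{-\gamma}$ (default $\gamma = 2.5$, the middle of the
  2–3 range reported for biological in-degree distributions; the exponent
  is a surfaced parameter) truncated to $[1, \min(n-1, 32)]$, then
  rescaled by random unit increments/decrements until the total equals
  $\mathrm{round}(\langle k\rangle n)$, making the realized mean exact up
  to rounding. The upper truncation reflects that in-degrees beyond a few
  dozen are not biologically observed; the rescaling absorbs the removed
  tail mass so the mean is unaffected.
* **Update-function families**: `uniform` truth tables are drawn only up
  to arity 6 — a uniformly random function on $k$ inputs requires $2^k$
  table entries, which is infeasible for heavy-tail arities — with random
  **nested canalyzing** functions (random input order, canalyzing values
  and outputs, non-degenerate last layer) used above that arity and
  available throughout as the biologically-motivated `nested-canalyzing`
  family.

What the generated corpora emulate: the sparsity, degree structure, and
update-rule statistics used for benchmarking steady-state solvers. What
they do not: curated regulatory logic, signed-interaction biases, or the
modular topology of real pathway models — so passing the random-network
suites demonstrates algorithmic correctness and scalability on
realistic-degree ensembles, not biological fidelity of any particular
model.

## Degenerate inputs and numerical choices

* A conjunction containing $x$ and $\neg x$ normalizes to constant 0 at
  construction; duplicate literals merge.
* A bare undeclared symbol is a parse error: unregulated nodes must be
  written as constants (pinning one environment) or self-inputs (leaving
  the environment free), which makes the treatment of external conditions
  explicit in the model text.
* The empty reduced network (everything eliminated) has exactly one,
  empty, steady state; backtracking rebuilds the full state from the trace
  alone.
* An inconsistent system yields the basis $\{1\}$ and the empty set; an
  empty equation system over $l$ variables yields all $2^l$ assignments
  (subject to the cap).
* States are bit vectors in declaration order (first variable = most
  significant bit); steady-state sets are deduplicated and sorted as
  binary integers, so all output is deterministic across runs.

## Problem sizes used in the test suite

Module property suites run hundreds of seeded random cases each; the
acceptance suite runs the method-versus-oracle comparison on 10 000 mixed
Kauffman/power-law networks with $n\le 14$, the FVS cross-check on 200
Kauffman $K=2$ networks with $n=50$, stage-boundary conservation on 2 000
networks whose AND-NOT form stays exhaustively scannable ($m\le 14$ — the
boundary counts are verified by full state-space scans, which fixes the
tractable corpus), solver-versus-scan equivalence on 2 000 AND-NOT
networks, and a single 1000-node sparse solve. These sizes were chosen so
the whole suite completes comfortably on a laptop-class single core while
still exercising every code path the larger published-model workloads use.

## Known limitations

* Dense networks (mean in-degree well above 3) can make the Gröbner step
  intractable — the method's own scaling limit; the timeout and cap exist
  to fail loudly there.
* The uniform-table family silently switches to nested canalyzing
  functions above arity 6 (documented above; unavoidable for uniform
  sampling).
* Only synchronous fixed points are computed; oscillatory attractors are
  invisible to this analysis.
* SBML-qual / GINsim formats are not read; the two plain-text dialects
  cover programmatic exchange.
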