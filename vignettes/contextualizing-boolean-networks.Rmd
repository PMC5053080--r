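---
title: "Contextualizing prior knowledge networks into asynchronous Boolean models"
author: "BoolContext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextualizing prior knowledge networks into asynchronous Boolean models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoolContext)
```

## The problem

A prior knowledge network (PKN) collects literature-curated regulatory
interactions between genes and proteins.  It is generic by construction: it
merges interactions observed in different cell types, tissues and
conditions, many of them indirect.  Turning a PKN directly into a dynamical
Boolean model therefore usually produces dynamics that do not match any one
biological context.  BoolContext addresses this by *contextualization*: it
searches the sub-networks of the PKN (subsets of its edges) for model
networks whose dynamical behaviour — stable phenotypes and the transitions
between them under perturbation — reproduces a training set of experimental
observations.

## The model

### Asynchronous Boolean networks

A model network is a signed directed graph.  Each node carries a Boolean
state; edges are activating or inhibiting.  The update target of a node is:

* **regulated node with activating in-edges** — 1 iff at least one activator
  is active *and* no inhibitor is active (inhibition dominant);
* **node with only inhibiting in-edges** — 1 iff no inhibitor is active;
* **input node (no regulators)** — its current value (unstimulated inputs
  are stable).

Updates are *asynchronous*: a transition of the state transition graph (STG)
flips exactly one node whose target differs from its current value.  The STG
is therefore non-deterministic.  A *perturbation* clamps a set of nodes
(over-expression = 1, knock-out = 0) for the duration of a simulation.

The rule for a node with only inhibitors is not uniquely determined by the
sign convention alone; the choice above (active unless inhibited) follows
the convention of the boolSim/genYsis family of asynchronous Boolean tools,
which this package is designed to interoperate with.

### Attractors and reachability

An *attractor* is a terminal strongly connected component of the STG: a
steady state (one state) or a cyclic attractor.  Attractors are read as the
stable phenotypes of the modelled system.  A cyclic attractor is summarized
by its *average state* (per-node mean over member states).  For a transition
between two perturbations P1 → P2, attractor A1 (under P1) *reaches*
attractor A2 (under P2) when some state of A1, with P2's clamped values
overwritten, has an STG path to A2 under P2.  The *attractor reachability
graph* collects these edges; it is the output of an in-silico experiment.

Two engines compute attractors:

* the **exact engine** enumerates all `2^f` states over the `f` non-clamped
  nodes and extracts terminal SCCs with Tarjan's algorithm (implemented in
  C++; successor lists are recomputed on the fly so memory stays linear in
  the number of states).  It refuses networks above a configurable cap
  (default 25 free nodes).
* the **stochastic engine** restarts up to `restarts` times (default 50).
  Each restart first attempts a bounded forward closure (cap `closureCap`,
  default 5000 states) of the start state: if the closure completes, its
  terminal SCCs are *certified* attractors of the full STG, because the
  closure is forward-closed.  If the cone overflows the cap, a random walk
  of up to `walkLength` steps (default 1000) descends towards an attractor
  first and the closure is retried from the walk's end.  On state spaces
  small enough to track (≤ 2^22 states), restarts are steered towards
  not-yet-visited states, which makes the search complete in practice on
  ten-node networks; on larger spaces completeness is only probabilistic.
  The engine never returns a false positive, and a fixed seed reproduces
  the result exactly.

### Training sets

A training set is a graph.  Each node pairs a perturbation with an
observation (Boolean states of some nodes measured at equilibrium); an edge
from node 1 to node 2 means "the first phenotype evolves into the second
upon the second perturbation".  Equal perturbations and equal observations
are allowed, so one condition exhibiting several stable phenotypes is
expressed as several nodes.

### The training distance f_T

A network *reproduces* the training set via an assignment of one attractor
to each training node subject to two constraints: (1) every training edge
must be realized as an attractor-reachability edge, and (2) the assignment
must be injective among training nodes sharing a perturbation (distinct
observed phenotypes of one condition are distinct attractors).  The distance
between an observation and an attractor is the mean absolute difference over
observed nodes between the observed value and the attractor's average state;
an observed node absent from the model network counts as constantly
inactive.  `f_T` is the minimum over feasible assignments of the mean
distance over training nodes — approximately, the fraction of observations
the network cannot reproduce.

The minimization decomposes into independent sub-problems: connected
components of the training graph, merged whenever two components share a
perturbation (the uniqueness constraint couples them).  Each sub-problem is
solved exactly by branch-and-bound with candidates ordered by distance; a
sub-problem with no feasible assignment contributes distance 1 per training
node, which keeps `f_T` in [0, 1].

### The fitness and its variants

Candidate networks are compared by the lexicographic tuple
`(f_T, -N_ess, N_nodes, -N_edges)`: first reproduce the training set, then
include as many user-listed *essential nodes* as possible, then use as few
nodes as possible, and finally — among equally small networks — keep as
many PKN edges as possible, so that the model stays close to the prior
knowledge and only drops edges contradicting the data.  The `min_edges`
variant `(f_T, -N_ess, N_edges)` instead minimizes edges without
constraining the node count; it converges more slowly and benefits from a
larger population (100 instead of 50).

## The optimizer

The search space for a PKN with M edges has 2^M sub-networks, so a genetic
algorithm over fixed-length bit-genomes (1 = edge kept) is used.  All
replicas start as the empty network.  Each iteration keeps the single best
replica unchanged (elitism) and refills the population by tournament
selection (size 2), uniform crossover (rate 0.9) and per-bit mutation at
rate 1/M; a run halts after more than `stagnationLimit` (default 10)
iterations without strict improvement of the best-ever fitness.  The
operator set is this package's own choice among standard alternatives;
correctness is asserted at the outcome level (recovery of `f_T = 0` on
self-consistent benchmarks, a
reproducible gap over random search at matched budgets, and agreement with
exhaustive enumeration on PKNs with ≤ 8 edges).

Identical genomes are cached within a run and never re-simulated.  Multiple
independent runs derive their seeds deterministically from a master seed;
the best `keepBest` runs become the model networks.  During fitness
evaluation the exact engine is used by default: at the network sizes this
package targets, exhaustive enumeration is both faster than stochastic
exploration and removes a noise source from the fitness; the stochastic
engine remains available (`engine = "stochastic"`) for networks beyond the
exact cap, mirroring the two-engine design of the original workflow.

## The in-silico benchmark

The benchmark generator turns a *gold standard* network into optimization
inputs, so that reconstruction quality can be measured against a known
truth:

1. **Transition table** — every single-node perturbation (each node forced
   to 1 and to 0), starting from each attractor of the unperturbed gold
   standard; each row is one reachability edge with before/after average
   states.
2. **Ideal PKN** — each row adds an edge from the perturbed node to every
   *other* observed node whose average state changes by more than 0.5, with
   sign = perturbation direction × sign of the change; the gold standard's
   own edges are unioned in.  (The perturbed node's own forced change is
   not an observation, so no self-edge arises from it.)
3. **Noisy PKNs** — a fraction q of edges is replaced by edges drawn
   without replacement from the signed complement over the same nodes
   (self-edges and opposite-sign partners allowed); the edge count is
   preserved exactly.
4. **Training sets** — for each background (mutant) perturbation the system
   starts from a reference state, settles into its initial attractor, and
   each stimulus is applied on top; every reached attractor becomes a
   training node and an edge from the background's initial node.
   Observations cover the essential nodes that are *stably* Boolean in the
   attractor (nodes oscillating inside a cyclic attractor are not
   reported), which guarantees the gold standard itself scores `f_T = 0`
   on its own training set.
5. **Corrupted training sets** — a fraction q of all observed node states
   is flipped, uniformly without replacement.
6. **Random sub-networks** — each PKN edge kept with probability 0.5; the
   baseline for both fitness and predictive power.

Synthetic gold standards are random signed digraphs with a chosen node
count, edge count and inhibiting fraction.  They emulate the size,
sparsity and sign mixture of curated signalling models, but not their
biological structure: no layered input–output organisation, no enrichment
for feedback motifs, and no biological meaning to the node labels.
Passing the benchmark therefore demonstrates that the optimizer recovers
dynamics-defining edges from idealized perturbation data — not that it
handles the additional ambiguities of real curated PKNs (missing
interactions, wrong signs from indirect effects, unmeasured nodes), which
the noise- and error-injection experiments only approximate.

## Predictive power: s_all

Given a model network and the gold standard, every single-node perturbation
of the k essential nodes (the unperturbed condition plus each node forced
to 1 and to 0 — `2k + 1` conditions) is simulated from every attractor of
the unperturbed gold standard.  The *average reached state* is the mean,
over all attractors reached (equally weighted), of their average states on
the essential nodes; model initial states are the gold attractor's states
projected onto the model's nodes with absent nodes set to 0.  With Δ the
mean Manhattan distance between model and gold average reached states over
all (perturbation, initial attractor) pairs,

&nbsp;&nbsp;&nbsp;&nbsp;`s_all = 1 − Δ / k`

equals 1 when the predictions always agree and 0 when they are consistently
opposite.  Since these experiments are not part of the training set, `s_all`
measures predictive power rather than goodness of fit.  The average over
(perturbation, initial) pairs is a flat mean over all pairs; reached
attractors are weighted equally, not by basin size.

**Combined predictions.**  For an ensemble of model networks, each
(perturbation, initial attractor, essential node) triple yields the
ensemble mean and population variance of the per-network average
prediction, and the error |ensemble mean − gold prediction|.  One dataset
of k essential nodes and a gold attractors yields `k(2k+1)a` records.  The
rank correlation between error and variance measures whether ensemble
disagreement — observable without knowing the truth — can stand in for the
unobservable prediction error.

## Numerical choices

* **State encoding** — states are unsigned integers (bit i = node i in
  lexicographic order), limiting networks to 30 nodes; the exact engine
  additionally caps free nodes at 25 by default and refuses larger inputs
  explicitly rather than degrading.
* **Canonical order** — attractor identity is the sorted tuple of member
  bit-strings; attractor lists are sorted by smallest member state, so all
  outputs are deterministic across engines and runs.
* **Degenerate inputs** — the empty network has one (empty) attractor, so
  `f_T` of an empty genome is well defined; perturbations of nodes absent
  from a sub-network clamp nothing; an observed node absent from the model
  contributes |observation − 0|.
* **Ties** — lexicographic fitness comparison breaks ties exactly in the
  stated component order; genuinely equal tuples compare equal, and the
  tournament keeps the first of equals.
* **Infeasible components** — distance 1 per training node, the worst
  possible, keeping `f_T` interpretable as a fraction not reproduced.

## Problem sizes used in the test-suite

The package's validation uses desk-scale instances chosen so that the exact
engine can serve as ground truth throughout: engine-equivalence checks on
one hundred 4–10-node random networks; self-recovery (generation of the
ideal PKN and training set followed by optimization back to `f_T = 0`) on
6–8-node gold standards; and the GA-versus-random comparison on a 10-node
gold standard whose ideal PKN has 66 edges — a 2^66 search space in which
random 0.5-sub-networks essentially never reproduce the training set, with
the genetic algorithm given a fixed budget of 25 iterations (≈ 1,300
evaluations) per run, and the random baseline exactly the same number of
evaluations.  Benchmarks of this kind in the literature run on curated
25-node signalling models with hundreds of independent optimization runs;
the sizes here are deliberately smaller so that exhaustive enumeration can
back every stochastic result, with the same workflow and the same
statistics.

## Limitations

* The sign-based update rule covers the boolSim-style model class only;
  arbitrary per-node Boolean functions, multi-valued logic and synchronous
  updates are out of scope.
* The stochastic engine guarantees no false positives but not completeness;
  on state spaces much larger than its closure cap its coverage depends on
  the walk length and restart count.
* GA hyperparameters are pragmatic defaults, not tuned optima; all are
  exposed in `gaParams()`.
* `f_T`'s branch-and-bound is exponential in the size of a training-graph
  component in the worst case; components in realistic training sets are
  small (one background's phenotypes).
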