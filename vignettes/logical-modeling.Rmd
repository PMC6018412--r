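---
title: "Multi-valued logical modeling of regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-valued logical modeling of regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvlogic)
```

## The formalism

`mvlogic` implements the multi-valued logical (Thomas) formalism for cellular
regulatory networks. A model is a *logical regulatory graph*: a set of
components, each with a discrete activity level in $0..\mathrm{max}$
(Boolean components have $\mathrm{max}=1$; multi-valued components use higher
maxima when one regulator acts differently on different targets), connected
by signed interactions, each carrying a *threshold* $\theta$. An interaction
is *active* when its source's level lies in the activity window
$[\theta, \theta' - 1]$, where $\theta'$ is the next higher threshold on the
same arc (or up to the source maximum when there is none). Level 0 never
activates an interaction.

Each regulated component $g$ carries logical rules: formulas over literals
(`reg` or `reg:θ`, combined with `!`, `&`, `|`) associated with target
values. In a state $x$ — a vector of levels, printed as a digit code such as
`0110` in declared node order — the *target level* of $g$ is the value of
the unique satisfied rule entry, or 0 when none is satisfied; components
without rules therefore relax to 0, and *input* components implicitly
maintain their level. A node whose target differs from its current level is
*called* to move one unit toward it.

Two modeling conventions deserve emphasis:

* **Negation is window negation.** `!p53` means "this interaction of p53 is
  inactive", i.e. the level lies outside the window of the interaction the
  literal resolves to — not "p53 = 0". With a threshold-2 interaction,
  `!p53` is true at levels 0 and 1.
* **Bare literals resolve through the interaction structure.** A bare
  literal is only legal when the regulator has a single interaction toward
  the rule's target; on a multi-threshold arc the threshold must be written
  explicitly (`Mdm2cyt:1`), because no unambiguous reading exists.

Rule entries of one node must be mutually exclusive; `validate_model()`
checks this exhaustively over the regulator subspace and reports a witness
assignment when two entries overlap. We reject overlaps rather than impose a
precedence because silent precedence hides modeling errors; the evaluation
layer additionally raises an error (with the witness state) should an
invalid model reach it.

## Updating schemes and transition graphs

A state's successors depend on the updating scheme:

| scheme | transitions from a state with call set $C$ |
|---|---|
| asynchronous | one successor per called node (unit step) |
| synchronous | one successor stepping all of $C$ |
| complete | one successor per non-empty subset of $C$ |
| sequential | one sweep over nodes in declared order |
| priority | calls gated by ranked node classes |

All updates are unitary: a multi-valued node moves by ±1 toward its target.
`build_stg()` assembles the state transition graph (STG) either over the
full product state space or restricted to the forward closure of
initial-state patterns (digit strings with `*` wildcards). Stable states are
exactly the out-degree-0 states, independently of the scheme.

Two points in the schemes were genuinely open and are fixed here as follows.
For the **sequential** scheme, the sweep re-evaluates each node's target
against the *partially updated* state, and each node moves at most one unit
per sweep — the simplest reading consistent with unitary updates. For
**priority classes**, each class has an integer rank and an inner mode;
among the classes containing a called node, those with the *smallest rank
value* fire (rank 1 before rank 2, matching the top-first presentation of
priority lists), classes of equal rank contributing their successor sets
independently, and concurrency inside a class resolved by its inner mode. A
single all-node class reproduces the plain asynchronous or synchronous
graph, which the test suite asserts.

Perturbations are clamps: `perturbation(DNAdam = 1)` constrains the target
level of a node into an interval (knock-down `[0,0]`, ectopic
`[max, max]`, or any range). Clamping rewrites behaviour, not structure, so
every analysis — successors, stable states, attractors — applies unchanged
to a perturbed model. Note that a clamp can *create* stable states that the
unperturbed model lacks (forcing p53 high in the packaged model freezes the
system at `2210`), so clamped stable sets are not in general projections of
the original set; the tests pin down both directions on examples.

## Stable states without the STG

`compute_stable()` avoids enumerating the product state space. For each node
$g$ it tabulates the *local stability relation* — the assignments over
$\{g\} \cup \mathrm{regulators}(g)$ with $f_g = x_g$ — and conjoins these
relations by relational joins, smallest first, then by greatest shared
variable set. When regulator sets are sparse the intermediate relations stay
far below the full product. The brute-force definition (enumerate all
states, keep those with an empty call set) remains the normative oracle: it
lives in the test helpers and the suite checks equality on randomized models
up to six nodes and maximal level 3.

## Compressing the dynamics

`scc_quotient()` lumps each strongly connected component (SCC) of the STG
into one node (igraph provides the SCC machinery), giving an acyclic graph
that preserves reachability between classes. `attractors()` returns its
terminal classes: singleton = stable state, larger = cyclic attractor.

The hierarchical transition graph (`build_htg()`) compresses further by
merging transient states. The published description — merging "linear
chains" — leaves the precise criterion open, and the printed six-node
result on the packaged model is the natural arbiter. A literal
reading (absorb a transient singleton into its unique successor class)
merges almost nothing on that model: most transient states keep two or more
successor classes, and 23 nodes survive. We therefore group transient
singleton classes by their *downstream fate*: the set of non-trivial
components (cyclic SCCs and stable states) they can reach. Along any
trajectory the fate set can only shrink, so the grouped graph is provably
acyclic; attractor classes are never merged, so attractors are preserved
exactly; and chains funnelling toward the same components collapse into
single nodes. On the packaged model this reproduces the published
compression exactly: six nodes — the stable state, a nine-state transient
cycle (all states under DNA damage), a six-state transient cycle (all
repaired), and three transient groups. The HTG does not preserve full
reachability, which matches its published characterization.

Member sets are rendered compactly by `state_patterns()`: positions where a
group of states takes every possible value collapse to `*`, and the
patterns' disjoint union is exactly the member set (an invariant the tests
re-expand and check).

## Circuit functionality

Regulatory circuits (simple directed cycles at arc level) drive the
qualitative dynamics: positive circuits (even number of inhibitions) are
required for multistationarity, negative ones for sustained oscillations.
`enumerate_circuits()` lists them with optional length/inclusion
constraints; enumeration is arc-level so that a multi-threshold arc does not
duplicate circuits — threshold choices are explored inside
`functionality_context()` instead.

For a threshold assignment $\theta_i$ (one per circuit arc), each circuit
node is confined to its switching window $\{\theta_i - 1, \theta_i\}$. An
assignment of levels to the *external* nodes is admissible when every
circuit arc is operational under it: for **every** placement of the other
circuit nodes inside their windows, moving the arc's source from
$\theta_i - 1$ to $\theta_i$ changes the target level of the arc's target.
The functionality context is the union of admissible assignments over
threshold choices; a circuit is functional iff its context is non-empty.
The universal ("for every placement") reading is a design choice; it
reproduces both published anchors on the packaged model — the
cross-inhibition circuit of p53 and nuclear Mdm2 is functional exactly at
`Mdm2cyt=1 & DNAdam=0`, and three of the four circuits are functional (two
positive, one negative). A circuit through a dual-signed arc is still
analysed; only its sign is reported as undetermined.

`interaction_functionality()` applies the same switching test per declared
interaction, classifying each as consistent, inconsistent or non-functional
with respect to its drawn sign — the standard sanity check that the graph
and the rules tell the same story.

## Model reduction

`reduce_model()` eliminates nodes one at a time. To eliminate $r$, the
target-level function of each of $r$'s targets is recomposed with $r$'s own
function (substituting $f_r(x)$ for $x_r$), tabulated over the new regulator
set, and then *re-synthesized exactly*: thresholds are re-derived as the
crossing points where the new function changes in some context, signs from
the observed change directions, and rules as disjunctions over the regulator
window boxes on which the function is constant. The eliminated node must not
be self-regulated (an input node counts as self-maintaining); eliminations
may create new self-regulation on kept nodes, which is allowed, and multiple
removals compose sequentially. Stable states of the reduced model are
exactly the projections of the original's — asserted on the packaged model
(`0110 → 010`) and on randomized eliminations against brute force on both
sides.

One corner is not expressible: a recomposed function that is constant and
non-zero has no formula in the literal-only grammar, and `reduce_model()`
raises a clear error rather than inventing structure. The random generator
below avoids the same corner by construction.

## The random-model generator

`random_model(n_nodes, max_level_cap, density, seed)` supports the
property-style tests. It draws each ordered node pair as an arc with the
given density (multi-valued sources may carry several thresholds), then
draws a random target-level function per regulated node, piecewise constant
on the regulators' window boxes, and synthesizes rules from it with the same
machinery as the reduction. Consequently generated models are valid by
construction: rule entries are mutually exclusive (disjoint boxes), every
literal resolves, and declared thresholds and signs agree with the rules.
Unregulated nodes occasionally become inputs. The defaults (maximal level
cap 2, density ≈ 0.45 in the test pool, 2–6 nodes) keep brute-force oracles
exact and fast — a few hundred states at most — while exercising
multi-valued windows, self-loops and inputs; randomized suites run at fixed
seeds, so failures reproduce.

What the generator does *not* emulate: the biological sparsity patterns of
curated networks (it draws arcs independently), rules with redundant or
non-functional declared interactions, and models large enough to stress the
state-space cap. Passing the randomized suites therefore demonstrates
semantic correctness of the machinery on small dense graphs, not performance
or realism at scale.

## Numerical and degenerate-input choices

* State codes require maximal levels ≤ 9 (one digit per node); validation
  enforces this.
* `build_stg()` guards enumeration with `max_states` (default $2^{20}$) and
  fails loudly with a dedicated condition class rather than exhausting
  memory; full-STG construction is intended for models of modest size.
* Successor lists, class orders and serialized output are deterministically
  ordered (node order, then subset order, then lexicographic state codes),
  so repeated runs are byte-identical.
* Empty models, rules referencing undeclared nodes, forward references in
  the text format, out-of-bounds thresholds and clamp ranges are rejected
  with positioned errors.
* The problem sizes used throughout the examples and tests are the packaged
  four-node network (36 states) and randomized models of 2–6 nodes; these
  are the sizes at which every oracle can be exhaustive.

## Known limitations

* The archive formats of interactive tools (GINML/SBML-qual and kin) are
  not read or written; the bespoke plain-text grammar and DOT/TSV exports
  are the interchange surface.
* Logical parameters (per-interaction-combination values) are not a separate
  entry mode; formulas are expressively equivalent.
* The HTG offers no reachability guarantees beyond what its construction
  preserves (attractors, fate partition).
* Reduction of a node whose recomposed targets lose all regulators (constant
  non-zero function) is rejected, as discussed above.
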