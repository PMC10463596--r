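---
title: "Majority-sign consistency modelling of signed regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Majority-sign consistency modelling of signed regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(majs)
```

## The modelling problem

A regulatory network is given as a signed directed interaction graph
$G = (V, E, \sigma)$: nodes are genes or proteins, and each directed edge is
an activation ($+$) or an inhibition ($-$). A differential-expression
experiment comparing two conditions supplies discrete observations for some
nodes: "+" over-expressed, "−" under-expressed, "0" unchanged. The question
the package answers is whether the network topology can explain the
observations, and — once any conflicts are repaired — what change of state
should be predicted for the unobserved nodes, and with what confidence.

The semantics is *majoritarian*. Each edge delivers an **influence** to its
target, the product of the edge sign and the source's sign
($I(s,v) = \sigma(s,v)\,\mu(s)$). A complete labelling assigns every node a
sign $\mu(v)$ and an integer confidence weight $\omega(v) \in [0, 100]$, and
must satisfy:

1. **Observation conservation** — observed nodes keep their experimental
   sign.
2. **Signed majority** — a node signed "+" or "−" must hold the strict
   majority among all its received influences.
3. **Balance** — a node signed "0" must receive either only 0-influences or
   equally many "+" and "−" influences.
4. **Weight assignment** — observed, unrepaired nodes have weight 100;
   repaired nodes have weight 0; otherwise the weight is the sum of the
   weights of the *supporting* parents (those whose influence equals the
   node's sign, or those delivering 0-influences for a "0"-signed node)
   divided by the node's total number of incoming edges.

When topology and data conflict, consistency is restored by attaching
**artificial influences** (signed ±1) to nodes, at most $K$ per node; these
count among the node's received influences when the majority rule is
re-checked, and a repaired node's weight drops to 0. The solver minimises
the *total* number of artificial influences and enumerates **all** optimal
answer sets. The **projection** step then summarises them per node:
majoritarian sign(s), per-sign answer-set counts, mean weight, and weight
standard deviation. Because every node must carry some sign in every answer
set, coverage of unobserved nodes is 100% by construction.

```{r toy}
toy <- toy_instance()
fit <- majs(toy$graph, toy$observations, K = 3)
summary(fit)
```

## Design choices where the semantics is open

Several corners of the rule set admit more than one reading; the package
fixes them as follows.

**Parentless nodes.** A node receiving no influence at all is vacuously
consistent with any sign, and carries weight 100: it acts as an input
source whose assigned state is taken at face value. This is what makes the
toy instance behave as published — node D's weight of 75 is
$(100+100+100)/4$, which requires its unobserved, parentless parent E to
weigh 100, and E indeed projects to mean weight 100 under both of its
admissible signs. (The alternative reading, weight 0 for unsupported
sources, would yield D = 50 and break the arithmetic.)

**Balanced "0" nodes.** Rule 4's "parents holding the majoritarian sign" is
read uniformly: for a "0"-signed node the supporters are the parents
delivering 0-influences. A node balanced purely by equal "+"/"−" counts
with no 0-influence parent therefore has weight 0 — the balance itself
carries no confidence mass.

**Cycles.** The weight operator is monotone on the integer lattice
$[0,100]^{|V|}$ once observed (100), repaired (0) and parentless (100)
nodes are clamped, so weights are defined as its least fixpoint, iterated
from zero. On acyclic graphs this coincides exactly with evaluation in
topological order (property-tested against an independent recursive
evaluator). Unclamped cycles settle at 0: a loop cannot generate
confidence about itself.

**Rounding.** Weights are rounded half-up to the closest integer at each
evaluation, keeping the whole labelling on the $3^{|V|} \times 101^{|V|}$
integer grid.

**Repair minimality and uniqueness.** For a *fixed* complete sign
assignment, node costs separate: the cheapest repair of a "+" node short
by $d$ votes is exactly $d$ positive influences, and a "0" node off-balance
by $d$ needs exactly $d$ influences on the minority side — any mixed-sign
multiset is strictly larger. The minimal repair multiset per node is
therefore unique, and answer sets are in bijection with the optimal sign
assignments. The solver exploits this with an exact depth-first
branch-and-bound over unobserved nodes (pruning on the per-node budget $K$
and on the incumbent total cost); an independent brute-force oracle instead
tries every $(a_+, a_-)$ combination against the rule predicate literally,
and the two are required to return identical answer-set collections on
randomized instances.

**Observed-but-repaired nodes.** The repair rule overrides the observation
rule for the weight (0, not 100) — a 0-weight is precisely how a repaired
node is recognisable in the output — while the observed sign itself is
never changed.

**Determinism.** Nodes are processed in lexicographic order and answer
sets are emitted sorted by their sign assignment, so repeated runs are
byte-identical; no randomness enters the solver.

## Comparing discrete predictions with continuous fold changes

A weighted prediction induces a three-component normal mixture
$M(x) = \sum_{s \in \{-,0,+\}} \phi_s N(x;\mu_s, \sigma_s)$: $\phi_s$ is
the fraction of optimal answer sets assigning sign $s$, $\mu_s$ is the
class mean of the discretised expression table, and $\sigma_s$ interpolates
linearly between a low-confidence and a high-confidence spread,
$\sigma(w) = \sigma_{hc}\,w/100 + \sigma_{lc}\,(1 - w/100)$, using the mean
weight of sign $s$ across answer sets (the projection reports one average
weight per sign; a weight dispersion term has no defined role and is not
used). An observed fold change $fc$ is scored by its band probability
$P(fc) = \int_{fc-\varepsilon}^{fc+\varepsilon} M(x)\,dx$, evaluated
exactly as Gaussian CDF differences rather than quadrature, and normalised
by the best achievable value
$P_{\max} = 2\Phi(\varepsilon/\sigma_{hc}) - 1$ (a single high-confidence
component centred on $fc$), giving $S(fc) = P(fc)/P_{\max} \in [0, 1]$.

The default parameter profile is the one calibrated on the HUVECS
endothelial RNA-Seq study: $\varepsilon = 0.005$ (fold-change units;
scores are insensitive to it, since numerator and denominator scale
together for narrow bands — see `significance_sweep()`),
$\sigma_{lc} = 0.5 \approx$ the distance between adjacent class means,
$\sigma_{hc} = 0.05$, and class means $\mu_- = -0.394$, $\mu_0 = 0$,
$\mu_+ = 0.489$. Six-level qualitative labels from sign-consistency tools
("notPlus", "CHANGE", ...) are adapted through
`mixture_from_iggy_label()`: unweighted, hence all components at
$\sigma_{hc}$, with two-sign labels splitting $\phi$ equally.

```{r score}
plot(fit, "D", fc = 0.3)
predict(fit, fc = c(D = 0.3, E = -0.4, G = 0.5))[c("node", "sign_maj", "fc", "S")]
```

## Discretisation of expression tables

Two rules are provided, matching common practice for the two assay types.
Fixed thresholds (RNA-Seq logFC): over 1.5 is "+", below −1.5 is "−",
within [−0.15, 0.15] is "0" — thresholds strict, band closed, so the
classes are disjoint for any admissible rule, and genes in no class stay
unobserved. Quartile thresholds (microarray FC): above the empirical Q3 is
"+", below Q1 is "−", within [0.99, 1.01] is "0"; quartiles use linear
interpolation between order statistics (`quantile()` type 7), the common
default, since no convention is fixed by the study design.

## What the synthetic generators emulate

`random_instance()` draws an Erdős–Rényi-style signed digraph (default 8
nodes, edge density 0.3, 25% inhibitions — the sparse, inhibition-poor
regime typical of curated signalling pathways), observes half the nodes
with uniformly random signs, and occasionally stacks an
activation/inhibition pair on one node pair to exercise the multigraph
semantics. Random observation signs make most instances inconsistent, which
is the point: they stress the repair machinery, and their minimal-cost
answer sets are verified against the exhaustive oracle.
`planted_consistent_instance()` instead propagates signs downstream by the
majority rule itself (ties resolving to "0"), yielding instances that are
consistent by construction, solve at cost 0, and contain the planted
labelling among their answer sets.

Neither generator reproduces the statistical structure of real expression
data — no correlation between graph distance and fold change, no
hub-dominated degree distribution, no measurement noise. Passing tests
therefore establish the combinatorial correctness of the semantics, the
optimality and completeness of the enumeration, and the analytical
correctness of the scoring — not biological validity on any particular
pathway.

## Problem sizes and limitations

The validation suite runs on instances of up to 8 nodes against the
exhaustive oracle (110 random instances, mixed cyclic/acyclic, budgets
$K \le 2$) and on the 10-node reference instance; these sizes keep the
oracle exact while covering every rule interaction. The branch-and-bound
scales well beyond that (cost pruning is strong because repairs are
expensive), but worst-case behaviour is exponential in the number of
unobserved nodes — pathway-scale graphs with ~50 unobserved nodes are
practical, genome-scale graphs are not. Other known limitations: repairs
are additions of influences only (no edge deletions or sign flips);
observed signs are kept even when they are the culprit, so heavily
inconsistent data should prompt scrutiny of the experiment or the network
rather than ever-larger budgets; and the enumeration count — not just the
optimum — is part of the output, so the `enumeration_cap` should be left
unset whenever the projection's answer-set ratios matter.
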