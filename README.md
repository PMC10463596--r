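# majs

Majority-sign consistency checking, minimal repair, and weighted prediction
for signed regulatory networks.

## The problem

A signalling or gene-regulatory network is commonly curated as a signed
directed graph: nodes are genes or proteins, edges are activations (`+`) or
inhibitions (`-`). A differential-expression experiment observes the change
of state of some nodes between two conditions — over-expressed (`+`),
under-expressed (`-`), or unchanged (`0`). Two questions follow:

1. **Consistency.** Can the network topology explain the observations? Under
   the *majority-sign* semantics, a node's sign must agree with the strict
   majority of the influences it receives (each influence being the product
   of an edge sign and the source node's sign); a `0` node must receive only
   null influences or a perfect `+`/`-` balance.
2. **Prediction.** When data and topology conflict, restore consistency by
   attaching a minimal total number of *artificial influences* (at most `K`
   per node), enumerate **all** optimal repaired solutions ("answer sets"),
   and project them into per-node predictions: each unobserved node gets its
   majoritarian sign(s) plus an integer confidence weight in [0, 100]
   (observed nodes weigh 100, repaired nodes 0, everything else is a
   supporter-weighted average propagated through the graph).

The weighted predictions can then be validated against the *continuous*
fold changes they abstract: each prediction induces a three-component
normal mixture (mixing coefficients from answer-set ratios, spreads
interpolated from the weights), and an observed fold change is scored by
its normalised band probability under that mixture, yielding a
significance score in [0, 1].

The intended audience is systems-biology and bioinformatics researchers
confronting discrete network models with expression data; the package is
also a compact, fully tested reference implementation of the semantics for
methods work.

## Worked example

The built-in 10-node instance (`toy_instance()`) has 8 signed edges and 7
observations; nodes D, E, G are unobserved, and observed node I contradicts
its activating parent J.

```r
library(majs)
toy <- toy_instance()
fit <- majs(toy$graph, toy$observations, K = 3)
fit
#> Majority-sign consistency model
#> Call: majs(graph = toy$graph, observations = toy$observations, K = 3)
#> Graph: 10 nodes, 8 edges; observations: 7 nodes; K = 3
#> Optimal answer sets: 2 (cost 2 artificial influences over 1 repaired node); 2-consistent
```

The conflict at I is resolved by two artificial inhibitions (one is not
enough to outvote the activation from J), and exactly two optimal answer
sets exist, differing only in the sign of the free input node E. The
projection summarises them per node:

```r
summary(fit)
#> ...
#> Repaired node(s): I
#>
#> Projected predictions:
#>  node sign_maj n_plus w_plus  sd_plus n_minus w_minus sd_minus n_zero w_zero ...
#>     D        +      2   62.5 17.67767       0       0        0      0      0
#>     E    0 / -      0    0.0  0.00000       1     100        0      1    100
#>     I        -      0    0.0  0.00000       2       0        0      0      0
```

D is predicted `+` in both answer sets with weights 75 and 50 (its weight
depends on whether E, an inhibitor of D, is `-` or `0`), hence mean 62.5
and standard deviation 17.68. E is a tie between `0` and `-` — a *weak*
prediction — at full weight, and repaired I carries weight 0. Supplying
fold changes scores each prediction's mixture:

```r
predict(fit, fc = c(D = 0.3, E = -0.4, G = 0.5))[1:3, c("node", "sign_maj", "fc", "P", "S")]
#>   node sign_maj   fc          P         S
#> 1    D        +  0.3 0.01255605 0.1576290
#> 2    E    0 / - -0.4 0.03954305 0.4964248
#> 3    G        +  0.5 0.07775741 0.9761691
```

`plot(fit, "D", fc = 0.3)` draws the mixture density with the fold change
marked. The joint search space over signs and weights is reported exactly
even when it exceeds double precision: `search_space_size(toy$graph)`
returns the 25-digit string `"6522683188340621511158049"` (= 303^10).

Other entry points: `read_interaction_graph()` / `read_sif()` and
`read_observations()` for files, `discretise_fixed()` /
`discretise_quartile()` for expression tables, `check_consistency()` for a
repair-free diagnosis, `brute_force_oracle()` as an independent exhaustive
solver for small instances, `random_instance()` /
`planted_consistent_instance()` for synthetic data, `run_pipeline()` for a
one-call file-to-file run, and `inst/scripts/majs-cli.R` as a command-line
front end.

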