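# mvlogic

Multi-valued logical modeling and analysis of cellular regulatory networks
in R, for systems biologists who want to study the qualitative dynamics of a
network when kinetic data are scarce.

A model is a *logical regulatory graph*: components with discrete activity
levels $0..\mathrm{max}$, signed interactions each carrying an activation
threshold $\theta$ (active on the window $[\theta, \theta'-1]$ up to the
next threshold), and logical rules (`!`, `&`, `|` over literals such as
`Mdm2cyt:2`) that give every component a *target level* in every state.
Nodes step one unit at a time toward their targets; an updating scheme
(asynchronous, synchronous, complete, sequential, or ranked priority
classes) decides which calls fire, yielding a *state transition graph*
(STG) whose sinks are the stable states and whose terminal strongly
connected components are the attractors.

The package provides:

* a plain-text model format (`.lrg`) with a documented grammar, plus DOT
  (Graphviz) and TSV exports;
* STG construction under all five updating schemes, with initial-state
  patterns (`0*1*`), perturbations (level clamps: knock-down, ectopic) and
  a state cap;
* direct stable-state computation by constraint propagation over per-node
  stability relations (no STG needed), checked against brute force;
* SCC quotient, attractor detection, and the hierarchical transition graph
  (HTG), an acyclic compression that lumps cycles and same-fate transient
  states while preserving attractors;
* regulatory-circuit enumeration with signs and *functionality contexts*
  (the external levels under which a feedback circuit is operational), and
  a declared-sign consistency check per interaction;
* model reduction by node elimination with exact re-synthesis of the
  targets' rules and interactions, preserving stable states;
* the four-node p53-Mdm2 network as a packaged example, a seeded
  random-model generator, and an `mvlogic` command-line tool
  (`stable`, `stg`, `htg`, `scc`, `circuits`, `reduce`,
  `check-interactions`).

## Worked example: the p53-Mdm2 network

The packaged model couples p53 (levels 0–2), cytoplasmic and nuclear Mdm2,
and DNA damage: nuclear Mdm2 degrades p53; p53 promotes cytoplasmic Mdm2
but blocks its nuclear import; damage destabilizes nuclear Mdm2 and is
repaired under high p53.

```r
library(mvlogic)
m <- p53_mdm2_model()

compute_stable(m)
#> [1] "0110"
```

The unique stable state `0110` (p53 = 0, Mdm2cyt = 1, Mdm2nuc = 1,
DNAdam = 0) is the resting cell. The full asynchronous dynamics and its
hierarchical compression:

```r
stg <- build_stg(m, "asynchronous")
stg
#> State transition graph (asynchronous updating): 36 state(s), 72 transition(s)
#> stable state(s): 0110

build_htg(stg)
#> Hierarchical transition graph: 6 node(s), 9 edge(s)
#>   i#10 [transient_chain]: *0*0, 0100, 0200, 1200, 2110
#>   i#9 [transient_chain]: *0*1, 0201, 1201, 2111
#>   ct#9 [cyclic_transient]: *101, *211, 0111, 1111, 2201
#>   0110 [stable]: 0110
#>   i#1 [transient_chain]: 0210
#>   ct#6 [cyclic_transient]: 11*0, 1210, 2100, 22*0
```

The two cyclic transient components are the biology: `ct#9` holds nine
states, all with DNA damage present, where p53 undergoes ample oscillations;
`ct#6` holds six damage-free states with smaller oscillations just after
repair, on the way back to rest. Circuit analysis explains which feedback
loops can act:

```r
for (ci in enumerate_circuits(m)) {
  fc <- functionality_context(m, ci)
  cat(sprintf("%s  sign=%s  functional=%s  %s\n",
      paste(c(ci$nodes, ci$nodes[1]), collapse = "->"),
      circuit_sign(ci), fc$functional, paste(fc$clauses, collapse = " | ")))
}
#> p53->Mdm2cyt->Mdm2nuc->p53  sign=negative  functional=TRUE  (always)
#> p53->Mdm2nuc->p53  sign=positive  functional=TRUE  Mdm2cyt=1 & DNAdam=0
#> p53->DNAdam->Mdm2nuc->p53  sign=negative  functional=FALSE
#> DNAdam->DNAdam  sign=positive  functional=TRUE  p53=0 | p53=1
```

Three of the four circuits are functional (two positive, one negative); the
p53/nuclear-Mdm2 cross-inhibition only operates at medium cytoplasmic Mdm2
without damage. Eliminating cytoplasmic Mdm2 compresses the model while
preserving its stable state:

```r
r <- reduce_model(m, "Mdm2cyt")
length(build_stg(r, "asynchronous")$states)  # 12 states instead of 36
compute_stable(r)
#> [1] "010"
```

The same analyses run from a shell, e.g.
`mvlogic stable inst/extdata/p53_mdm2.lrg` or
`mvlogic htg --format dot inst/extdata/p53_mdm2.lrg | dot -Tsvg > htg.svg`.

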