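# complexfix

Audit and repair molecular complexes in BioPAX Level 3 pathway exports.

BioPAX requires complexes to be *flat*: a complex may not contain another
complex among its components, unless that inner complex is a *black box*
(empty component list, composition unknown). Curated pathway databases
nonetheless export *recursive* complexes — complexes of complexes — which
lengthen the path from a complex to its molecular constituents, break
participant queries, and hide redundancy between records that share the
same composition under different nestings.

`complexfix` is for curators and pathway-analysis developers who work with
BioPAX files. It:

* **classifies** every complex as `BLACK_BOX`, `VALID_NON_RECURSIVE` or
  `INVALID_RECURSIVE`, with composition depth and an interaction census;
* **fixes** invalid complexes by collapsing the leaves of the composition
  tree into direct components with correct *global* stoichiometric
  coefficients, preserving every other statement in the file;
* **detects redundancy**: maximal cliques of complexes with identical
  flattened components, coefficients and cellular location;
* **reads and writes** BioPAX Level 3 as RDF/XML (`.owl`) and Turtle
  (`.ttl`), round-tripping untouched statements verbatim;
* **simulates** fixtures with known ground truth for testing.

## The core computation

For a complex *y* with direct components *C(y)* and direct-edge
coefficients *c_y(p)*, the global stoichiometric coefficient of entity *z*
in *y* is

    S_z(z) = 1
    S_y(z) = 0                                if y ≠ z and C(y) = ∅
    S_y(z) = Σ_{p ∈ C(y)} c_y(p) · S_p(z)     otherwise

i.e. the sum over all composition paths y → z of the product of edge
coefficients along each path, computed as a memoized dynamic program over
the composition DAG. If *X* contains α *Y* plus β *Z* directly and *Y*
contains γ *Z*, then S_X(Z) = αγ + β. Fixing replaces each invalid
complex's components with its leaves (atomic entities and black boxes),
each carrying S_root(leaf); redundancy detection then groups complexes by
the canonical signature (sorted leaf multiset, coefficients, cellular
location), whose equality classes are exactly the maximal cliques of the
pairwise-redundancy graph.

## Worked example

```r
library(complexfix)
library(dplyr)

# a synthetic pathway export with planted structure
sim <- bp_simulate(fixture_config(seed = 1))
sim$graph
#> <biopax_graph>
#>   entities:    43
#>   complexes:   18 (1 black-box)
#>   component edges: 43 (0 with defaulted stoichiometry)
#>   interactions: 5
#>   residual statements: 115

bp_census(sim$graph)
#> # A tibble: 3 × 2
#>   category                n
#>   <chr>               <int>
#> 1 BLACK_BOX               1
#> 2 VALID_NON_RECURSIVE     8
#> 3 INVALID_RECURSIVE       9

fx <- bp_fix_all(sim$graph)
fx
#> <bp_fix> flattened 9 invalid recursive complexes; 9 unchanged

bp_report(sim$graph, fx$graph)
#> <bp_report>
#>   complexes: 18, invalid: 9 (50%)
#>   direct components: 2.4 (SD 1.0) max 4  ->  3.1 (SD 1.2) max 5
#>   redundancy: 1 pairs (1 cliques)  ->  4 pairs (2 cliques)
```

Half the simulated complexes violate the flat-composition rule; after
flattening, every complex lists its molecular constituents directly (depth
≤ 1), the mean number of direct components rises accordingly, and
redundancy detection finds the planted group — three complexes that nested
the same composition differently and therefore looked distinct before
fixing. `tidy(fx)` gives the per-complex before/after table, `glance(fx)`
the totals, and `autoplot()` works on fix, redundancy and report objects.

Single quantities are available directly:

```r
g <- bp_simulate(fixture_config(seed = 1))$graph
cx <- bp_classify(g) |> filter(category == "INVALID_RECURSIVE") |> pull(iri)
bp_global_stoichiometry(g, cx[[1]])      # full flattening of one complex
bp_leaves(g, cx[[1]])                    # its leaf set
```

Files go through `read_biopax()` / `write_biopax()`; a command-line
wrapper at `exec/complexfix` exposes `classify`, `fix`, `redundancy`,
`synth`, `report` and `report-batch` subcommands over the same functions,
e.g.

```sh
exec/complexfix fix export.owl -o fixed.owl --report fix_report.tsv
exec/complexfix redundancy fixed.owl --pairs pairs.tsv --cliques cliques.tsv
```

## Package layout

* `R/biopax.R`, `R/rdfxml.R`, `R/turtle.R` — graph model and serialization
* `R/classify.R` — categories, depth, census, interaction participation
* `R/fix.R` — global stoichiometry and flattening
* `R/redundancy.R` — signatures, pairs, maximal cliques, annotations
* `R/synthetic.R` — fixture generator and brute-force oracle
* `R/report.R` — before/after summary statistics
* `vignettes/complex-flattening.Rmd` — the model, its assumptions, and
  every design decision
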