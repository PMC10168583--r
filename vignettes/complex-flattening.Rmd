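---
title: "Flattening recursive complexes and detecting redundancy in BioPAX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flattening recursive complexes and detecting redundancy in BioPAX}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexfix)
library(dplyr)
```

## The problem

BioPAX Level 3 describes pathway knowledge as an OWL/RDF graph. Among its
physical entities, a *complex* is a set of molecules bound together
noncovalently, listed through the `component` property with per-edge
`Stoichiometry` nodes. The specification requires complexes to be **flat**:
a complex must not have another complex among its components, the one
exception being *black-box* complexes, whose component list is empty
because their make-up is unknown. The rationale is that nesting would
implicitly encode an assembly order that curators never intended to assert.

Curated databases nonetheless export *recursive* complexes — complexes
containing complexes that themselves have components. These records evade
standard validators, artificially lengthen the path from a complex to its
molecular constituents, cause false negatives in participant queries
("interactions having a participant that is a complex composed of A"), and
hide redundancy: the same molecular composition curated twice under
different bracketings looks like two unrelated records.

`complexfix` addresses all three consequences: it classifies complexes
against the flat-composition rule, rewrites invalid ones into conformant
flat records with correct global stoichiometry, and detects redundant
complexes as maximal cliques of identical flattened composition.

## Classification

Every complex falls in exactly one category:

* `BLACK_BOX` — the component list is empty (composition depth 0);
* `VALID_NON_RECURSIVE` — it has components and every complex-typed
  component is a black box (depth 1);
* `INVALID_RECURSIVE` — some component is a complex that itself has
  components (depth ≥ 2).

Depth is the longest path from the complex to any of its leaves in the
directed composition graph. The composition structure is a DAG, not a
tree: one physical entity can be a component of several parts of the same
recursive complex. A complex that (transitively) contains itself is a
curation error of a different kind; such cycles are detected by strongly
connected components, reported by IRI, and quarantine only the complexes
on or above the cycle — everything else is still analyzed.

## Global stoichiometry

Let $c_y(p)$ be the stoichiometric coefficient on the direct edge from
complex $y$ to component $p$, and $C(y)$ the set of direct components of
$y$. The global coefficient $S_y(z)$ — the number of occurrences of entity
$z$ in $y$ — satisfies

$$
S_z(z) = 1, \qquad
S_y(z) = 0 \;\text{ if } y \neq z \text{ and } C(y) = \emptyset, \qquad
S_y(z) = \sum_{p \in C(y)} c_y(p)\, S_p(z) \;\text{ otherwise.}
$$

Equivalently, $S_y(z)$ sums over every composition path from $y$ to $z$
the product of edge coefficients along the path. In the canonical
three-node example — $X$ holds $\alpha\, Y$ and directly $\beta\, Z$,
while $Y$ holds $\gamma\, Z$ — this gives
$S_X(Z) = \alpha\gamma + \beta$; with $\alpha=2,\ \gamma=3,\ \beta=1$,
seven occurrences.

The implementation is a memoized dynamic program over the DAG (each node
visited once), so diamonds — a sub-complex shared by several branches —
cost nothing extra. The package also ships
`bp_expand_brute_force()`, a deliberately naive exhaustive path
enumeration kept free of memoization. It is exponential in the worst case
and exists purely as an independent oracle: the test suite compares the
two on hundreds of random DAGs, and the fixture generator computes its
ground truth with it.

## Fixing

`bp_fix_all()` rewrites each invalid complex in four steps: (i) its direct
components become exactly the leaves of its composition tree — non-complex
entities and black-box complexes; (ii) edges to intermediate complexes are
deleted; (iii) each leaf edge gets the global coefficient $S_{root}(leaf)$;
(iv) every other statement about the complex is preserved verbatim.
Design choices worth stating explicitly:

* **Black boxes are leaves.** They are the one complex kind allowed as a
  component, so flattening keeps them as direct components rather than
  erasing them.
* **Intermediate complexes are not deleted.** Only the *edges* from the
  fixed root are rewritten; the intermediates remain standalone records,
  since they may participate in interactions in their own right.
* **Every root is flattened against the original topology**, memoized
  across roots, so the result is independent of fixing order; the
  operation is idempotent and afterwards every complex has depth 0 or 1.
* **Missing stoichiometry defaults to 1** and is flagged
  (`explicit = FALSE`) at load time; 1 is the minimal biologically
  meaningful count. Any global coefficient whose computation touched a
  defaulted edge is flagged in the fix report
  (`n_defaulted_coefficients`), so the assumption stays auditable.
* **Non-integer coefficients are accepted** and propagated as-is; the
  data model does not require integers.
* **Fresh `Stoichiometry` nodes are minted** for rewritten edges at
  serialization time (deterministically, from the complex IRI), while
  untouched edges keep their original nodes — so files that needed no
  fixing round-trip statement-for-statement.

## Redundancy

Two complexes are redundant when they have exactly the same components
with the same stoichiometric values and the same cellular location. After
flattening, the composition signature is canonical (sorted component
multiset plus location), so redundancy detection is a grouping operation,
and the groups are maximal cliques of the pairwise-equality graph.
The accounting identities follow: a group of size $k$ contributes
$k(k-1)/2$ pairs and $k-1$ complexes *in excess* (records beyond one
canonical representative), and summed over groups,
excess = distinct members − groups.

Three decisions shape the signature:

* **Coefficients compare exactly** (no tolerance) by default; curated
  coefficients are integral. `coef_digits` rounds to significant digits
  first for floating data — rounding, rather than pairwise tolerance,
  keeps equality transitive.
* **Absent location is a value, not a wildcard**: a complex without a
  location annotation can only match another location-less complex.
  Location demonstrably discriminates otherwise-identical records, and
  treating missing as "matches anything" would merge records on no
  evidence. `ignore_location = TRUE` switches the constraint off.
* **Black-box complexes are never redundant**: an empty component list
  carries no compositional evidence.

Although the transitivity argument makes connected components sufficient,
`bp_group_pairs()` verifies the clique property of every component and
aborts with an internal-consistency error if it fails — a cheap guard
that would catch any future non-transitive signature change; the tests
additionally cross-check the groups against Bron–Kerbosch maximal-clique
enumeration from igraph. `bp_annotate_same_composition()` materializes
each group as symmetric `hasSameCompositionAs` statements in a dedicated
annotation namespace, leaving the original BioPAX statements untouched.

## The synthetic generator

`bp_simulate(fixture_config(...))` builds BioPAX graphs with known ground
truth; it is first-class, tested code, and the basis of most of the test
suite. It emulates the structural features that make real exports hard:

* nested composition DAGs with a chain guaranteeing the target depth
  (`max_depth`, default 4; depths up to 10 occur in real exports);
* shared sub-complexes with probability `p_shared` (default 0.25),
  because real composition structures are DAGs and tree-only fixtures
  would under-test the path-summing recursion;
* black boxes (`p_blackbox`, default 0.1), integer coefficients 1–5,
  a small vocabulary of cellular locations with occasional absent
  annotations, and interaction stubs for participation counting;
* planted redundancy groups: a flat component multiset re-bracketed
  randomly into different binary nestings at one shared location — the
  exact mechanism by which real redundancy hides behind recursion. Inner
  edges carry coefficient 1 and each leaf's unique path carries its
  target coefficient, so members provably share their flattened
  composition.

Ground truth (categories, depths, flattened compositions, redundancy
groups) is computed inside the generator by direct one-hop checks,
plain recursion and exhaustive path enumeration — code paths disjoint
from the analysis modules they are used to judge. Generation is a pure
function of the config (seed included) and leaves the caller's RNG
stream untouched.

What passing on these fixtures does *not* show: conformance of the
reader to every RDF/XML and Turtle construct in the wild (the parser
covers the subset BioPAX exports use; collections and anonymous nodes
are rejected explicitly), correctness of the participation-property
census against any specific database's property usage, or performance
at the scale of a full per-species export (the suite runs at tens of
complexes per fixture; the algorithms are linear in edges apart from
the deliberately exponential oracle).

## Numerical and degenerate-input choices

* Coefficients are doubles throughout; serialization uses a fixed
  lexical form (`"2.0"`, 15 significant digits for non-integers) so
  generation is byte-deterministic.
* The population standard deviation (divisor $n$) is used for
  direct-component statistics; at realistic complex counts the estimator
  choice is immaterial but it is fixed for determinism. Black-box
  complexes contribute a count of 0 to these statistics.
* Percentages and means are kept at full precision internally; `print()`
  rounds (means to one decimal, percentages to integers).
* Empty graphs: a census of zero complexes is all-zero; component
  statistics on a complex-free graph are an explicit error rather than
  NaN.
* Files not using Level 3 vocabulary are rejected outright rather than
  best-effort parsed; component edges to undeclared entities are a
  referential-integrity error naming the offending IRIs.

## Problem sizes in the checks

The acceptance script regenerates everything it reports at run time:
500 random DAGs (2–10 complexes each, branching ≤ 4, coefficients 1–5,
diamonds enabled) for the stoichiometry/oracle agreement, ten simulated
exports of 18 complexes for post-fix topology and idempotence, planted
groups of sizes 2–6 for the clique arithmetic, and one 30-complex export
for the end-to-end pipeline. These sizes exercise every structural
feature listed above while keeping the exhaustive oracle exact.

## Known limitations

* The paired significance test comparing before/after component counts is
  out of scope; the fix report exposes the paired per-complex counts so
  any such test can be run externally.
* Redundancy is detected, never merged: rewriting interactions that
  reference redundant records is a curation decision, not a mechanical
  one.
* Cross-database identity resolution (external complex catalogues) is out
  of scope.
* The interaction census counts one hop of the participation properties
  (`left`, `right`, `controller`, `cofactor`, `product`, `template`,
  `participant`); nested participants are not re-expanded.
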