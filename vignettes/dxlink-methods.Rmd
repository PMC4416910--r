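---
title: "Exact link invariants of DNA double-crossover polyhedra"
author: "dxlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact link invariants of DNA double-crossover polyhedra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxlink)
```

## The problem

DNA polyhedra assembled from n-point-star tiles are modelled topologically
as *double-crossover polyhedral links*: each edge of the polyhedron carries
a double-crossover DNA duplex, and the two antiparallel backbone strands
make the structure an oriented link. For the 4-turn constructions, each
original edge contributes 16 crossings, so even the cube gives a link with
192 crossings — far beyond what generic skein-tree Homfly software can
handle. `dxlink` computes the Homfly polynomial of these links exactly, via
two reductions:

1. **Truncation by substitution.** The combinatorics of the link live on
   the *truncation* G' of the underlying cubic graph G (insert two vertices
   on each edge, then replace each degree-3 star by a triangle). The chain
   polynomial of G' with its two natural labels — `a` on images of original
   edges, `b` on new triangle edges — is obtained from the chain polynomial
   of the much smaller G by a term-by-term substitution, never by expanding
   G' itself.
2. **Tangle substitution.** Substituting exact rational expressions in the
   Homfly variables (v, z) for `a`, `b` and the flow variable ω turns
   Ch(G') into the Homfly polynomial of the link, up to an explicit
   prefactor.

## The chain polynomial and its calculus

For a graph with edges labeled a, b, c, ..., the chain polynomial is

    Ch(G) = Σ_Y  F_Y(1 − ω) · π_{E−Y},

the sum over all edge subsets Y of the flow polynomial of the spanning
subgraph ⟨Y⟩ (evaluated at 1 − ω) times the product of the labels *not* in
Y. It is multilinear in the labels; its constant term is the flow
polynomial of G; the flow polynomial of anything with a bridge is 0.

`chainPolynomial()` computes Ch by deletion–contraction,
`Ch(G) = (a − 1) Ch(G − a) + Ch(G/a)`, with the base cases: edgeless graph
→ 1, loop labeled a → factor (a − ω), and multiplicativity over connected
components and cut vertices. Numerical choices:

* **Pivot rule.** The pivot is always the lexicographically smallest
  non-loop label, so the recursion tree (and any memoized intermediate)
  is reproducible run to run.
* **Memoization** keys on the exact labeled edge list with vertices renamed
  by first appearance — never on isomorphism classes. Correctness over
  speed; the largest graph the oracle tests expand directly has 18 edges.
* **Exactness.** Chain-polynomial coefficients are integers held in
  doubles and every operation checks they stay below 2^53, so this layer
  is exact without big-number machinery.

Two transforms from the chain-polynomial calculus are exposed because the
truncation theorem is proved with them: `chainReplace()` substitutes a
label by a chain of labels (and `chainCollapse()` inverts it), and
`yDelta()` performs the Y–Δ transform

    P xyz + A x + B y + C z + V  ↦
    P(xyz−ω) + A(yz+x−ω−1) + B(xz+y−ω−1) + C(xy+z−ω−1) + V(x+y+z−ω−2).

`yDelta()` *validates* the decomposition (a term carrying exactly two of
x, y, z would contradict the cut-set property) instead of assuming it: a
malformed input produces a loud structural error, not a silently wrong
polynomial. One deliberate deviation: `chainReplace()` refuses chain
labels that collide with existing ones *unless* `allowMerge = TRUE`,
because the truncation construction itself needs the merged, non-
multilinear form (every edge mapped to `b_i · a · b_j` with shared
symbols).

## Truncation by substitution

For cubic loop-free G with n vertices and m edges, every term of Ch(G)
with label support U and coefficient F contributes

    F · a^|U| · (b³−ω)^p · (b²+b−ω−1)^q · (3b−ω−2)^(n−p−q)

to Ch(G'), where p and q count vertices of G meeting U in exactly 3 and
exactly 1 edges. Incidence is counted per edge *instance* in the original
graph, so parallel edges (the theta graph) work; loops are rejected
because the two-end-vertex replacement underlying the construction is
ill-defined for them (the graph-level `structuralTruncate()` still accepts
loops — only the substitution does not). A vertex meeting U in exactly two
edges cannot occur for a genuine chain polynomial; if it does, the input
was not `chainPolynomial(G)` and an internal-consistency error is raised.

The result is stored both factored (powers of the three ω–b factors per
term) and expanded in powers of a and b; the constructor recomputes the
expansion as a self-check. `truncateChainStepwise()` exposes the two
intermediate polynomials of the proof (per-vertex b-powers; then x = b³,
y = b). The package's strongest internal oracle compares the substitution
against a completely independent route: `structuralTruncate()` builds G'
explicitly, deletion–contraction computes its chain polynomial over all
3m per-edge labels, and `collapseToTwoLabel()` merges the labels to a and
b. The two-label polynomials agree exactly for the theta graph (9-edge
prism) and K4 (18-edge truncated tetrahedron).

## From Ch(G') to the Homfly polynomial

With δ = (1/v − v)/z, the negative (all-left-handed, the antiparallel DNA
orientation) double-crossover 4-turn link on an x-edge cubic plane graph P
has

    P_L(v, z) = δ⁻¹ · [ (v⁻³ − v⁻¹ − 2z²(v + v⁻¹)) / (v¹³ − v¹⁵) ]^x · Ch(P')

after substituting ω = 1 − δ², b = v⁴ and
a = (v⁻² − 1 − z²(1+v²+v⁴+v⁶)) / (v⁻² − 1 − 2z²(v²+1)) in Ch(P').
The implementation is fraction-free: the a-denominator is cleared by
multiplying each a^j group by its complementary power, everything is
assembled as one Laurent polynomial, and each denominator factor is then
divided out once, exactly — a nonzero remainder anywhere aborts the run,
so a substitution bug cannot produce a plausible-looking wrong
polynomial. The positive link is v → −1/v (an involution), per the
construction's mirror symmetry, not an independent formula.

Coefficients reach ~10^23, so this layer runs on a dedicated
arbitrary-precision integer and sparse bivariate Laurent-polynomial core
(compiled; decimal strings at the R boundary). No floating point is
involved anywhere in the pipeline.

Specializations: the Conway polynomial is the exact evaluation at v = 1
(surviving negative z-powers are an error — they always cancel for true
Homfly polynomials); the Jones polynomial substitutes v = s², z = s − 1/s
in s = t^(1/2), clearing negative z-powers by an exact univariate division
at the end. Even-component links therefore print half-integer t-powers,
which is why the Jones type stores s-exponents.

Braid-index bounds combine the Morton–Franks–Williams inequality
span_v/2 + 1 ≤ b(L) with Ohyama's bound b(L) ≤ 1 + c(L)/2 for
non-splittable links, using the 16-per-edge crossing count of the 4-turn
diagram. For the theta, tetrahedral and hexahedral links the bounds
coincide (25, 49, 97), determining the braid index exactly.

## A worked example

```{r theta}
theta <- builtinGraph("theta")
chainPolynomial(theta)
P <- homflyDoubleCrossover(theta)
conway(P)
braidIndexBounds(P, diagramCrossingNumber(theta))
```

The Conway polynomial of each of the three named links is a single
monomial (−37632 z⁷, −1078984704 z¹³, −748419423085264896 z²⁵); its
magnitude is the cofactor of the link's linking matrix, but the
linking-matrix cross-check itself needs per-component linking numbers
that are out of scope here — the suite only asserts that the
lowest-degree Conway coefficient is a nonzero integer.

## What the random fixtures do and do not establish

`randomCubicMultigraph()` draws a seeded uniform pairing of the 3n
half-edge stubs, the standard configuration model for random cubic
multigraphs. Defaults in the tests use n ∈ {2, 4, 6} (m ≤ 9 edges): small
enough that the brute-force subset-sum oracle (2^m flow polynomials) and
flow-counting oracle (enumerating nowhere-zero Z_k flows for k = 2..4)
stay exact and fast, yet rich enough to exercise loops, parallel edges,
bridges and disconnected deletions. Loops are kept — the chain-polynomial
layer must handle them — and the truncation-substitution tests draw the
first loop-free pairing from a deterministic seed scan. A green suite
establishes the algebraic identities on these graphs; it does not
establish anything about plane embeddings (the package never stores one),
nor about orientations other than the two handedness conventions, nor
about turn numbers other than 4.

Two scope notes on the test machinery. The planarity invariant
("truncation preserves planarity of the builtin plane graphs") is checked
with a certificate that is sound and complete for Hamiltonian graphs —
backtracking Hamiltonian cycle plus bipartiteness of the chord
interlacement graph — because no installed R package provides a general
planarity test; all builtin truncation images (and the K3,3 control) are
Hamiltonian, so nothing is skipped. And the Theorem-2 cancellation
property is sampled on loop-free fixtures with up to 9 edges rather than
all fixtures with 12, purely to keep the default test run fast; the
12-edge case is covered by the cube itself.

## Degenerate inputs and tie-breaks

* Edgeless graphs: Ch = 1, flow = 1 (empty product); a single vertex is a
  valid graph.
* Disconnected graphs: Ch is treated as multiplicative over components,
  the natural extension of the cut-vertex product rule (the subset-sum
  definition factorizes).
* A loop adds 2 to its vertex's degree, so `loop + bridge + loop` is a
  cubic multigraph; loops are never bridges and each loop is its own
  2-edge-connected block.
* JSON round-trips are canonical: vertex order, edge order and labels are
  preserved byte-for-byte.
* Exit codes of the `dxlink` script: 0 success, 2 usage, 3 violated
  precondition or bad input file, 4 internal consistency failure.

## Known limitations

* Only 3-regular (cubic) graphs: the truncation substitution for
  n-regular graphs and protein polyhedra is out of scope.
* Only 4-turn (16 crossings per edge) links; other turn numbers would
  change the tangle closures and the crossing count.
* Deletion–contraction is exponential in edge count; the intended regime
  is ≲ 20 edges for direct chain polynomials, which the substitution
  theorem then leverages to 3× larger truncated graphs.
* The linking-matrix/cofactor verification of the Conway leading
  coefficient is not implemented (component structure and pairwise
  linking numbers are not derived).
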