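# dxlink — exact link invariants of DNA double-crossover polyhedra

DNA polyhedra self-assembled from n-point-star motifs (tetrahedra, cubes,
and relatives) are, topologically, *double-crossover polyhedral links*:
each polyhedron edge carries a double-crossover duplex, and the
antiparallel backbone strands orient the link. Their invariants
distinguish isomers and quantify chirality, but the diagrams are huge —
the 4-turn construction puts 16 crossings on every edge, so the cube link
already has 192 crossings, far beyond generic skein-tree Homfly software.

`dxlink` is for the structural-DNA / mathematical-chemistry audience that
needs these invariants exactly. It computes, with exact integer
arithmetic throughout:

* the **chain polynomial** Ch(G) of a labeled cubic multigraph by
  deletion–contraction:
  `Ch(G) = Σ_Y F_Y(1−ω) π_{E−Y}`, with `Ch(G) = (a−1)Ch(G−a) + Ch(G/a)`;
* the **two-label chain polynomial of the truncation** G′ directly by the
  substitution theorem: a term with support U and coefficient F maps to
  `F a^|U| (b³−ω)^p (b²+b−ω−1)^q (3b−ω−2)^(n−p−q)`,
  where p and q count vertices meeting U in 3 resp. 1 edges — so the
  192-crossing cube link needs only the 12-edge cube graph;
* the **Homfly polynomial** `P_L(v, z)` of the negative (or positive)
  double-crossover 4-turn link via
  `P_L = δ⁻¹ [(v⁻³−v⁻¹−2z²(v+v⁻¹))/(v¹³−v¹⁵)]^x Ch(G′)` with
  `ω = 1−δ²`, `b = v⁴`,
  `a = (v⁻²−1−z²(1+v²+v⁴+v⁶))/(v⁻²−1−2z²(v²+1))`, `δ = (v⁻¹−v)/z`;
* the **Conway** (`∇_L(z) = P_L(1, z)`) and **Jones**
  (`V_L(t) = P_L(t, √t − 1/√t)`) specializations, and **braid-index
  bounds**: Morton–Franks–Williams `span_v/2 + 1 ≤ b(L)` against Ohyama's
  `b(L) ≤ 1 + c(L)/2`.

Coefficients grow past 10^18, so the Laurent-polynomial layer runs on a
compiled arbitrary-precision core; every rational substitution is cleared
fraction-free and divided out exactly, with any nonzero remainder
treated as a fatal internal error rather than rounded away.

## A worked example

```r
library(dxlink)
theta <- builtinGraph("theta")     # 2 vertices, 3 parallel edges a1 a2 a3
chainPolynomial(theta)
#> ChainPolynomial: 5 terms in 3 labels
#>   [1] w + w^2
#>   [a1] - w
#>   [a1*a2*a3] 1
#>   [a2] - w
#>   [a3] - w
```

That is `a1 a2 a3 − ω(a1+a2+a3) + ω² + ω`. Pushing it through the
truncation substitution and the tangle substitution gives the invariants
of the 48-crossing theta-graph link:

```r
P <- homflyDoubleCrossover(theta)  # exact, 94 terms
conway(P)
#> ConwayPolynomial: -37632*z^7
jones(P)
#> JonesPolynomial: -t^(-7/2) + 7*t^(-9/2) - 28*t^(-11/2) + 84*t^(-13/2)
#>   - 210*t^(-15/2) + 462*t^(-17/2) - 924*t^(-19/2) + 1713*t^(-21/2) + ...
braidIndexBounds(P, diagramCrossingNumber(theta))
#> BraidIndexBounds: span_v = 48, MFW lower = 25, Ohyama upper = 25
#>   braid index determined exactly: 25
```

The single-term Conway polynomial (coefficient −37632) and the exact
braid index 25 are the published values for this link; the half-integer
t-powers of the Jones polynomial reflect the link's even component count.
The same calls with `builtinGraph("tetrahedron")` and
`builtinGraph("cube")` give `-1078984704*z^13` / braid index 49 and
`-748419423085264896*z^25` / braid index 97, the cube case in about two
seconds.

Graphs can also be loaded from JSON
(`{"vertices":[0,1], "edges":[[0,1,"a1"], ...]}`, see `loadGraph()`), and
the whole pipeline is scriptable through the installed `dxlink`
executable (`graph stats|truncate`, `chain`, `truncate-chain`, `homfly`,
`invariants`, `fixtures random-cubic`), which emits deterministic JSON
reports.

## Verification layers

The implementation is cross-checked along independent routes: the
substitution result for the theta graph and K4 equals the raw
deletion–contraction chain polynomial of their structurally truncated
graphs (9-edge prism, 18-edge truncated tetrahedron) with labels
collapsed; chain polynomials on random cubic multigraphs are compared
against the brute-force subset-sum definition and flow polynomials
against enumerated nowhere-zero Z_k flow counts; the tangle closure
expressions satisfy their defining skein identities symbolically.

`scripts/acceptance.R` recomputes the headline published quantities from
scratch — the Conway coefficients and selected Homfly/Jones coefficients
of the theta, tetrahedral and hexahedral links — by running the full
pipeline, and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Cubic (3-regular) plane graphs and 4-turn double-crossover links only;
loops are accepted by the graph layer but not by the truncation
substitution (the construction needs distinct end-vertices). See the
methods vignette (`vignettes/dxlink-methods.Rmd`) for the model,
numerical choices, and known limitations.
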