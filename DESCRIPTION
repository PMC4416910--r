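Package: dxlink
Title: Chain Polynomials and Homfly Invariants of DNA Double-Crossover
    Polyhedral Links
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact computation of the chain polynomial of labeled cubic
    multigraphs by deletion-contraction, of the two-label chain polynomial of
    their truncations by direct substitution, and of the Homfly, Conway and
    Jones polynomials and braid-index bounds of the DNA double-crossover
    4-turn links built on such graphs.  All arithmetic is exact: chain
    polynomials use machine-integer coefficients and the link polynomials use
    an arbitrary-precision Laurent-polynomial core, so coefficients of
    magnitude 1e18 and beyond are reproduced digit for digit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    jsonlite,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
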