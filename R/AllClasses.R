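# Central S4 classes.  Chain-polynomial terms are stored in a canonical
# form: term keys are the term's labels (with multiplicity) sorted bytewise
# and joined by the unit separator "\x1f"; the empty key "" is the constant
# term; coefficients are omega-polynomial numeric vectors (see omega.R) with
# no trailing zeros; zero terms are dropped and keys are sorted.  Two chain
# polynomials are mathematically equal iff their slots are identical.

.SEP <- "\x1f"
# key of the constant (label-free) term; impossible as a real label key
# because labels are non-empty and never contain the separator
.KEMPTY <- "\x1f"

#' Labeled multigraph
#'
#' A multigraph with 0-based integer vertex ids and uniquely labeled edges.
#' Loops and parallel edges are allowed; a loop contributes 2 to the degree
#' of its vertex.  Edge order is part of the object and survives file
#' round-trips.
#'
#' @slot vertices integer vector of vertex ids (ordered, unique).
#' @slot edges data.frame with columns `u`, `v` (integer vertex ids) and
#'   `label` (character, unique within the graph).
#' @seealso [labeledMultigraph()], [builtinGraph()], [loadGraph()]
#' @export
setClass("LabeledMultigraph",
  representation(vertices = "integer", edges = "data.frame"),
  validity = function(object) {
    e <- object@edges
    if (!identical(names(e), c("u", "v", "label")))
      return("edges must have columns u, v, label")
    if (anyDuplicated(object@vertices))
      return("duplicate vertex ids")
    if (nrow(e)) {
      if (!is.integer(e$u) || !is.integer(e$v) || !is.character(e$label))
        return("edge columns must be integer, integer, character")
      bad <- setdiff(c(e$u, e$v), object@vertices)
      if (length(bad))
        return(sprintf("edge endpoint references undeclared vertex %d", bad[1]))
      if (anyDuplicated(e$label))
        return(sprintf("duplicate edge label '%s'",
                       e$label[duplicated(e$label)][1]))
      if (any(grepl(.SEP, e$label, fixed = TRUE)))
        return("edge labels must not contain the reserved separator \\x1f")
      if (any(!nzchar(e$label)))
        return("edge labels must be non-empty")
    }
    TRUE
  }
)

#' Structural summary of a multigraph
#'
#' @slot nVertices,nEdges integer counts.
#' @slot degreeSequence integer degrees, one per vertex (loops count twice).
#' @slot isCubic logical, TRUE when every degree is 3.
#' @slot bridges character labels of cut-edges.
#' @slot blocks list of character vectors partitioning the edge labels into
#'   2-edge-connected blocks (each bridge is its own block).
#' @export
setClass("GraphStats",
  representation(nVertices = "integer", nEdges = "integer",
                 degreeSequence = "integer", isCubic = "logical",
                 bridges = "character", blocks = "list"))

#' Polynomial in the flow variable omega
#'
#' Dense integer coefficient vector, constant term first.  Flow-polynomial
#' values and chain-polynomial coefficients use this type; coefficients are
#' exact (checked to stay below 2^53).
#'
#' @slot coef numeric vector, coefficient of omega^0, omega^1, ...;
#'   numeric(0) is the zero polynomial.
#' @export
setClass("OmegaPolynomial", representation(coef = "numeric"),
  validity = function(object) {
    n <- length(object@coef)
    if (n && object@coef[n] == 0) return("trailing zero coefficient")
    if (n && any(object@coef != round(object@coef)))
      return("coefficients must be integers")
    TRUE
  }
)

#' Chain polynomial of a labeled graph
#'
#' The chain polynomial is the sum over all edge subsets Y of the flow
#' polynomial (in omega, evaluated at 1 - omega) of the spanning subgraph
#' with edge set Y, times the product of the labels of the remaining edges.
#' Chain polynomials of graphs are multilinear in the labels; label
#' substitutions ([chainReplace()]) may merge labels, so the class also
#' carries terms with exponents above 1 (keys then repeat a label).
#'
#' @slot terms named list; each name encodes the labels of a term (sorted,
#'   "\x1f"-joined, possibly with repeats), each element is an
#'   omega-polynomial coefficient vector.
#' @slot labels character vector, the label universe of the source graph.
#' @export
setClass("ChainPolynomial",
  representation(terms = "list", labels = "character"),
  validity = function(object) {
    nm <- names(object@terms)
    if (length(object@terms) && is.null(nm))
      return("terms must be named by their label set")
    if (!identical(nm, sort(nm, method = "radix")))
      return("term keys must be radix-sorted")
    used <- unique(unlist(strsplit(nm[nm != .KEMPTY], .SEP, fixed = TRUE)))
    if (length(setdiff(used, object@labels)))
      return("term uses a label outside the label universe")
    TRUE
  }
)

#' Two-label chain polynomial of a truncated cubic graph
#'
#' The chain polynomial of the truncation of a cubic graph, with every image
#' of an original edge labeled `a` and every new triangle edge labeled `b`.
#' Stored both factored -- per original-edge-subset term, as a power product
#' of the three omega-b factors (b^3 - w), (b^2 + b - w - 1), (3b - w - 2) --
#' and expanded in powers of `a` and `b`; agreement of the two forms is
#' checked on construction.
#'
#' @slot terms named list keyed "aexp:bexp" with omega-polynomial values
#'   (the expanded form).
#' @slot factored list of records `list(coef, aexp, p, q, r)`: coefficient
#'   omega-polynomial and exponents of the three factors.
#' @slot n,m integer vertex and edge counts of the original graph.
#' @slot source character name of the source graph ("" when unknown).
#' @export
setClass("TwoLabelChainPolynomial",
  representation(terms = "list", factored = "list",
                 n = "integer", m = "integer", source = "character"))

#' Exact Laurent polynomial in v and z
#'
#' Sparse Laurent polynomial with arbitrary-precision integer coefficients,
#' the value type of the Homfly polynomial pipeline.  Coefficients are held
#' as decimal strings; all arithmetic happens in compiled code and is exact.
#' Terms are kept in descending z-degree, then descending v-degree.
#'
#' @slot vexp,zexp integer exponent vectors.
#' @slot coef character vector of decimal integer coefficients.
#' @seealso [laurentPolynomial()], [homflyDoubleCrossover()]
#' @export
setClass("LaurentPolynomial2",
  representation(vexp = "integer", zexp = "integer", coef = "character"),
  validity = function(object) {
    if (length(object@vexp) != length(object@zexp) ||
        length(object@vexp) != length(object@coef))
      return("vexp, zexp and coef must have equal length")
    if (any(object@coef == "0"))
      return("zero coefficients must not be stored")
    TRUE
  }
)

#' Conway polynomial (integer polynomial in z)
#'
#' @slot zexp integer exponents (descending).
#' @slot coef character decimal coefficients.
#' @export
setClass("ConwayPolynomial",
  representation(zexp = "integer", coef = "character"))

#' Jones polynomial in s = t^(1/2)
#'
#' Laurent polynomial in s with integer exponents; the exponent of t is half
#' the exponent of s, so even-component links print half-integer t-powers.
#'
#' @slot sexp integer s-exponents (descending).
#' @slot coef character decimal coefficients.
#' @export
setClass("JonesPolynomial",
  representation(sexp = "integer", coef = "character"))

#' Ratio of two Laurent polynomials in v and z
#'
#' Unreduced rational expression; equality is decided by cross-multiplication.
#'
#' @slot num,den LaurentPolynomial2 numerator and denominator.
#' @export
setClass("RationalLaurent",
  representation(num = "LaurentPolynomial2", den = "LaurentPolynomial2"),
  validity = function(object) {
    if (length(object@den@coef) == 0L) return("zero denominator")
    TRUE
  }
)

#' Invariants of the two covering tangles
#'
#' Numerator and denominator closures, multipliers mu and weights w of the
#' double-crossover tangle T1 (covering original edges) and the vertical
#' 2-crossing tangle T2 (covering truncation edges), as rational expressions
#' in v and z, plus delta = (1/v - v)/z.
#'
#' @slot nuT1,deT1,nuT2,deT2,muT1,muT2,wT1,wT2,delta RationalLaurent.
#' @export
setClass("TangleInvariants",
  representation(nuT1 = "RationalLaurent", deT1 = "RationalLaurent",
                 nuT2 = "RationalLaurent", deT2 = "RationalLaurent",
                 muT1 = "RationalLaurent", muT2 = "RationalLaurent",
                 wT1 = "RationalLaurent", wT2 = "RationalLaurent",
                 delta = "RationalLaurent"))

#' Braid-index bounds from the Homfly polynomial
#'
#' Lower bound from the Morton-Franks-Williams inequality
#' (span_v/2 + 1 <= b(L)), upper bound from Ohyama's crossing-number bound
#' (b(L) <= 1 + c(L)/2); `exact` is filled when they coincide.
#'
#' @slot spanV,mfwLower,crossingNumber,ohyamaUpper integer.
#' @slot exact integer, NA when the bounds differ.
#' @export
setClass("BraidIndexBounds",
  representation(spanV = "integer", mfwLower = "integer",
                 crossingNumber = "integer", ohyamaUpper = "integer",
                 exact = "integer"),
  validity = function(object) {
    if (object@mfwLower != object@spanV %/% 2L + 1L)
      return("mfwLower must equal spanV/2 + 1")
    if (object@ohyamaUpper != 1L + object@crossingNumber %/% 2L)
      return("ohyamaUpper must equal 1 + crossingNumber/2")
    if (!is.na(object@exact) && object@exact != object@mfwLower)
      return("exact value must equal the coinciding bounds")
    TRUE
  }
)
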