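# Homfly polynomial of the double-crossover 4-turn link built on a cubic
# plane graph, from the two-label chain polynomial of the truncation.
#
# Substitutions (negative link, all crossings left-handed):
#   w = 1 - delta^2,  delta = (1/v - v)/z
#   a = (v^-2 - 1 - z^2 (1 + v^2 + v^4 + v^6)) / (v^-2 - 1 - 2 z^2 (v^2+1))
#   b = v^4
# and the whole polynomial is multiplied by
#   delta^-1 * [ (v^-3 - v^-1 - 2 z^2 (v + v^-1)) / (v^13 - v^15) ]^x ,
# x = edge count of the original graph.  Everything is carried out by
# clearing denominators over exact integers and dividing out each factor at
# the end; every division is checked to be exact.

.hfPieces <- function() {
  lp <- laurentPolynomial
  list(
    deltaNum = lp(c(-1L, 1L), c(0L, 0L), c(1, -1)),            # 1/v - v
    omega = lp(c(0L, -2L, 0L, 2L), c(0L, -2L, -2L, -2L),
               c(1, -1, 2, -1)),                               # 1 - delta^2
    aNum = lp(c(-2L, 0L, 0L, 2L, 4L, 6L), c(0L, 0L, 2L, 2L, 2L, 2L),
              c(1, -1, -1, -1, -1, -1)),
    aDen = lp(c(-2L, 0L, 2L, 0L), c(0L, 0L, 2L, 2L), c(1, -1, -2, -2)),
    wNum = lp(c(-3L, -1L, 1L, -1L), c(0L, 0L, 2L, 2L), c(1, -1, -2, -2)),
    vDen = lp(c(13L, 15L), c(0L, 0L), c(1, -1)),               # v^13 - v^15
    z = lp(0L, 1L, 1),
    zero = lp(),
    one = lp(0L, 0L, 1)
  )
}

#' Homfly polynomial of a double-crossover 4-turn link
#'
#' Builds the oriented double-crossover 4-turn link on the cubic loop-free
#' graph `G` (each original edge covered by the double-crossover tangle,
#' each truncation edge by the vertical 2-crossing tangle) and returns its
#' Homfly polynomial, exactly.  The default orientation is the negative
#' (all-left-handed) link of the antiparallel DNA backbone convention; the
#' positive link is obtained by the variable change v -> -1/v.
#'
#' @param G a cubic, loop-free [LabeledMultigraph-class].
#' @param orientation `"negative"` (default) or `"positive"`.
#' @param twoLabel optionally a precomputed [truncateChain()] result.
#' @return A [LaurentPolynomial2-class] in v and z.
#' @examples
#' P <- homflyDoubleCrossover(builtinGraph("theta"))
#' conway(P)  # -37632 z^7
#' @export
homflyDoubleCrossover <- function(G, orientation = c("negative", "positive"),
                                  twoLabel = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is(G, "LabeledMultigraph"))
  if (is.null(twoLabel)) twoLabel <- truncateChain(G)
  stopifnot(is(twoLabel, "TwoLabelChainPolynomial"))
  pieces <- .hfPieces()
  m <- twoLabel@m
  x <- m

  terms <- twoLabel@terms
  maxOm <- max(vapply(terms, length, integer(1))) - 1L
  omPow <- vector("list", maxOm + 1L)
  omPow[[1]] <- pieces$one
  for (k in seq_len(maxOm)) omPow[[k + 1L]] <- omPow[[k]] * pieces$omega

  # group by a-exponent: M_j = sum over terms coef * v^(4 bexp) * omega^k
  M <- vector("list", m + 1L)
  for (nm in names(terms)) {
    ab <- .tlKeyParse(nm)
    F <- terms[[nm]]
    acc <- pieces$zero
    for (k in seq_along(F)) {
      if (F[k] == 0) next
      acc <- acc + .lp2Mono(F[k], 4L * ab[2], 0L) * omPow[[k]]
    }
    j <- ab[1] + 1L
    M[[j]] <- if (is.null(M[[j]])) acc else M[[j]] + acc
  }

  aNumPow <- vector("list", m + 1L)
  aDenPow <- vector("list", m + 1L)
  aNumPow[[1]] <- aDenPow[[1]] <- pieces$one
  for (k in seq_len(m)) {
    aNumPow[[k + 1L]] <- aNumPow[[k]] * pieces$aNum
    aDenPow[[k + 1L]] <- aDenPow[[k]] * pieces$aDen
  }

  # numerator of Ch(P') over the common denominator aDen^m
  Q <- pieces$zero
  for (j in 0:m) {
    if (is.null(M[[j + 1L]]) || .lp2ZeroQ(M[[j + 1L]])) next
    Q <- Q + aNumPow[[j + 1L]] * aDenPow[[m - j + 1L]] * M[[j + 1L]]
  }

  num <- pieces$z * (pieces$wNum ^ x) * Q
  P <- laurentDivExact(num, pieces$deltaNum)
  for (i in seq_len(x)) P <- laurentDivExact(P, pieces$vDen)
  for (i in seq_len(m)) P <- laurentDivExact(P, pieces$aDen)

  if (orientation == "positive") P <- mirrorLink(P)
  P
}

#' Conway polynomial from a Homfly polynomial
#'
#' Exact evaluation at v = 1.  Negative z-powers must cancel at v = 1
#' (they always do for an actual Homfly polynomial); if any survive, the
#' input was malformed and an error is raised.
#'
#' @param P a [LaurentPolynomial2-class].
#' @return A [ConwayPolynomial-class].
#' @export
conway <- function(P) {
  stopifnot(is(P, "LaurentPolynomial2"))
  out <- tryCatch(.lp2_conway(.lp2Raw(P)),
                  error = function(e) .stopPrecondition(
                    "not a Homfly polynomial: %s", conditionMessage(e)))
  new("ConwayPolynomial", zexp = as.integer(out$zexp),
      coef = as.character(out$coef))
}

#' Jones polynomial from a Homfly polynomial
#'
#' Substitutes v = t, z = sqrt(t) - 1/sqrt(t), computed exactly in the
#' variable s = t^(1/2); a t-exponent is half the stored s-exponent, so
#' links with an even number of components show half-integer t-powers.
#'
#' @param P a [LaurentPolynomial2-class].
#' @return A [JonesPolynomial-class].
#' @export
jones <- function(P) {
  stopifnot(is(P, "LaurentPolynomial2"))
  out <- tryCatch(.lp2_jones(.lp2Raw(P)),
                  error = function(e) .stopPrecondition(
                    "not a Homfly polynomial: %s", conditionMessage(e)))
  new("JonesPolynomial", sexp = as.integer(out$sexp),
      coef = as.character(out$coef))
}

#' @describeIn conway Coefficient of z^zexp, as a decimal string.
#' @param zexp integer exponent(s).
#' @export
conwayCoefficient <- function(P, zexp) {
  stopifnot(is(P, "ConwayPolynomial"))
  idx <- match(as.integer(zexp), P@zexp)
  ifelse(is.na(idx), "0", P@coef[idx])
}

#' @describeIn jones Coefficient of s^sexp = t^(sexp/2), as a decimal
#'   string.
#' @param sexp integer s-exponent(s).
#' @export
jonesCoefficient <- function(P, sexp) {
  stopifnot(is(P, "JonesPolynomial"))
  idx <- match(as.integer(sexp), P@sexp)
  ifelse(is.na(idx), "0", P@coef[idx])
}

#' Crossing number of the 4-turn double-crossover diagram
#'
#' Each original edge carries a 16-crossing double-crossover tangle in the
#' 4-turn construction, so the standard diagram of the link on an m-edge
#' cubic graph has 16 m crossings (192 for the cube, 96 for the
#' tetrahedron).
#'
#' @param G a cubic [LabeledMultigraph-class].
#' @return Integer crossing count.
#' @export
diagramCrossingNumber <- function(G) {
  stopifnot(is(G, "LabeledMultigraph"))
  if (!.isCubic(G))
    .stopPrecondition("crossing-number formula requires a cubic graph")
  16L * nEdges(G)
}

#' Braid-index bounds from Homfly span and crossing number
#'
#' Lower bound (Morton-Franks-Williams): span_v / 2 + 1.  Upper bound
#' (Ohyama, non-splittable links): 1 + c(L) / 2.  When the two coincide
#' the braid index is determined exactly.
#'
#' @param P a nonzero [LaurentPolynomial2-class] Homfly polynomial.
#' @param crossingNumber even crossing number of a diagram of the link.
#' @return A [BraidIndexBounds-class].
#' @examples
#' P <- homflyDoubleCrossover(builtinGraph("theta"))
#' braidIndexBounds(P, diagramCrossingNumber(builtinGraph("theta")))
#' @export
braidIndexBounds <- function(P, crossingNumber) {
  stopifnot(is(P, "LaurentPolynomial2"))
  crossingNumber <- as.integer(crossingNumber)
  if (crossingNumber %% 2L != 0L)
    .stopPrecondition("crossing number must be even, got %d", crossingNumber)
  sp <- spanV(P)
  span <- sp[2] - sp[1]
  if (span %% 2L != 0L)
    .stopPrecondition(
      "odd v-span %d would give a non-integer braid-index bound", span)
  lower <- span %/% 2L + 1L
  upper <- 1L + crossingNumber %/% 2L
  new("BraidIndexBounds", spanV = span, mfwLower = lower,
      crossingNumber = crossingNumber, ohyamaUpper = upper,
      exact = if (lower == upper) lower else NA_integer_)
}

setMethod("show", "BraidIndexBounds", function(object) {
  cat(sprintf("BraidIndexBounds: span_v = %d, MFW lower = %d, Ohyama upper = %d\n",
              object@spanV, object@mfwLower, object@ohyamaUpper))
  if (!is.na(object@exact))
    cat(sprintf("  braid index determined exactly: %d\n", object@exact))
  else
    cat("  bounds do not coincide; braid index undetermined\n")
})
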