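# Invariants of the two covering tangles of the 4-turn construction, as
# exact rational expressions in v and z.

.ratNew <- function(num, den) new("RationalLaurent", num = num, den = den)

.ratFrom <- function(P) .ratNew(P, laurentPolynomial(0L, 0L, 1))

.ratMul <- function(A, B) .ratNew(A@num * B@num, A@den * B@den)

.ratAdd <- function(A, B) .ratNew(A@num * B@den + B@num * A@den,
                                  A@den * B@den)

.ratSub <- function(A, B) .ratNew(A@num * B@den - B@num * A@den,
                                  A@den * B@den)

.ratInv <- function(A) {
  if (.lp2ZeroQ(A@num)) .stopPrecondition("inverse of the zero expression")
  .ratNew(A@den, A@num)
}

.ratDiv <- function(A, B) .ratMul(A, .ratInv(B))

#' Equality of rational Laurent expressions
#'
#' Decided exactly by cross-multiplication.
#'
#' @param A,B [RationalLaurent-class] objects.
#' @return TRUE or FALSE.
#' @export
rationalEqual <- function(A, B) {
  .lp2ZeroQ(A@num * B@den - B@num * A@den)
}

#' @describeIn rationalEqual Numerator accessor.
#' @param x a RationalLaurent.
#' @export
ratNum <- function(x) x@num

#' @describeIn rationalEqual Denominator accessor.
#' @export
ratDen <- function(x) x@den

setMethod("show", "RationalLaurent", function(object) {
  cat("RationalLaurent:\n  num:", formatLaurent(object@num, 6),
      "\n  den:", formatLaurent(object@den, 6), "\n")
})

#' Closure values and skein invariants of the covering tangles
#'
#' The double-crossover tangle T1 covers the images of original edges; the
#' vertical 2-crossing tangle T2 covers the new triangle edges.  For a
#' 2-tangle T with numerator closure Nu(T) and denominator closure De(T),
#' the multiplier and weight are
#' mu(T) = (delta P_Nu(T) - P_De(T)) / (delta^2 - 1) and
#' w(T) = (delta P_De(T) - P_Nu(T)) / (delta P_Nu(T) - P_De(T)),
#' with delta = (1/v - v)/z the value of a split unknot.  The closure
#' values are the closed forms of the 4-turn construction:
#' P_Nu(T1) = delta^-1 (1-v^-4)^2 + delta^-1 2 v^-4 (1-v^-4) + delta v^-8,
#' P_De(T1) = delta^-2 (1-v^-4)^2 + 2 v^-4 (1-v^-4) + delta^2 v^-8,
#' P_Nu(T2) = 1,  P_De(T2) = delta^-1 (1-v^-4) + delta v^-4;
#' mu and w are computed from them via the defining identities.
#'
#' @return A [TangleInvariants-class].
#' @export
tangleInvariants <- function() {
  lp <- laurentPolynomial
  one <- .ratFrom(lp(0L, 0L, 1))
  delta <- .ratNew(lp(c(-1L, 1L), c(0L, 0L), c(1, -1)),
                   lp(0L, 1L, 1))          # (1/v - v) / z
  A <- .ratFrom(lp(c(0L, -4L), c(0L, 0L), c(1, -1)))   # 1 - v^-4
  v4i <- .ratFrom(lp(-4L, 0L, 1))
  v8i <- .ratFrom(lp(-8L, 0L, 1))
  two <- .ratFrom(lp(0L, 0L, 2))
  dInv <- .ratInv(delta)

  nuT1 <- .ratAdd(.ratAdd(
    .ratMul(dInv, .ratMul(A, A)),
    .ratMul(dInv, .ratMul(two, .ratMul(v4i, A)))),
    .ratMul(delta, v8i))
  deT1 <- .ratAdd(.ratAdd(
    .ratMul(.ratMul(dInv, dInv), .ratMul(A, A)),
    .ratMul(two, .ratMul(v4i, A))),
    .ratMul(.ratMul(delta, delta), v8i))
  nuT2 <- one
  deT2 <- .ratAdd(.ratMul(dInv, A), .ratMul(delta, v4i))

  d2m1 <- .ratSub(.ratMul(delta, delta), one)
  mu <- function(nu, de) .ratDiv(.ratSub(.ratMul(delta, nu), de), d2m1)
  wgt <- function(nu, de) .ratDiv(.ratSub(.ratMul(delta, de), nu),
                                  .ratSub(.ratMul(delta, nu), de))

  new("TangleInvariants",
      nuT1 = nuT1, deT1 = deT1, nuT2 = nuT2, deT2 = deT2,
      muT1 = mu(nuT1, deT1), muT2 = mu(nuT2, deT2),
      wT1 = wgt(nuT1, deT1), wT2 = wgt(nuT2, deT2),
      delta = delta)
}

#' @describeIn tangleInvariants Accessor: one of "nuT1", "deT1", "nuT2",
#'   "deT2", "muT1", "muT2", "wT1", "wT2", "delta".
#' @param x a TangleInvariants.
#' @param what slot name.
#' @export
tangleValue <- function(x, what) {
  stopifnot(is(x, "TangleInvariants"))
  slot(x, match.arg(what, c("nuT1", "deT1", "nuT2", "deT2",
                            "muT1", "muT2", "wT1", "wT2", "delta")))
}

setMethod("show", "TangleInvariants", function(object) {
  cat("TangleInvariants for the 4-turn double-crossover construction\n")
  cat("  P_Nu(T2) num:", formatLaurent(object@nuT2@num, 4), "\n")
  cat("  mu(T2)  num:", formatLaurent(object@muT2@num, 4), "\n")
  cat("  (use tangleValue(x, what) for the full expressions)\n")
})
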