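# R face of the exact Laurent-polynomial core (src/laurent.cpp).

.lp2Wrap <- function(raw) {
  new("LaurentPolynomial2", vexp = as.integer(raw$vexp),
      zexp = as.integer(raw$zexp), coef = as.character(raw$coef))
}

.lp2Raw <- function(P) {
  list(vexp = P@vexp, zexp = P@zexp, coef = P@coef)
}

# coefficients may be numerics (must be exact integers < 2^53) or decimal
# strings
.coefToString <- function(coef) {
  if (is.character(coef)) return(coef)
  if (any(abs(coef) >= 2^53))
    .stopInternal("numeric coefficient too large for exact conversion")
  if (any(coef != round(coef)))
    .stopUsage("coefficients must be integers")
  sprintf("%.0f", coef)
}

#' Construct an exact Laurent polynomial in v and z
#'
#' @param vexp,zexp integer exponent vectors.
#' @param coef coefficients: integer-valued numerics (below 2^53) or
#'   decimal strings of any length.  Repeated exponent pairs are summed.
#' @return A [LaurentPolynomial2-class].
#' @examples
#' laurentPolynomial(c(-1, 1), c(-1, -1), c(1, -1))  # delta = (1/v - v)/z
#' @export
laurentPolynomial <- function(vexp = integer(0), zexp = integer(0),
                              coef = character(0)) {
  .lp2Wrap(.lp2_build(as.integer(vexp), as.integer(zexp),
                      .coefToString(coef)))
}

.lp2Mono <- function(coef, vexp = 0L, zexp = 0L) {
  laurentPolynomial(vexp, zexp, coef)
}

.lp2ZeroQ <- function(P) length(P@coef) == 0L

setMethod("+", signature("LaurentPolynomial2", "LaurentPolynomial2"),
  function(e1, e2) .lp2Wrap(.lp2_add(.lp2Raw(e1), .lp2Raw(e2))))

setMethod("-", signature("LaurentPolynomial2", "LaurentPolynomial2"),
  function(e1, e2) .lp2Wrap(.lp2_sub(.lp2Raw(e1), .lp2Raw(e2))))

setMethod("-", signature("LaurentPolynomial2", "missing"),
  function(e1, e2) .lp2Wrap(.lp2_neg(.lp2Raw(e1))))

setMethod("*", signature("LaurentPolynomial2", "LaurentPolynomial2"),
  function(e1, e2) .lp2Wrap(.lp2_mul(.lp2Raw(e1), .lp2Raw(e2))))

setMethod("^", signature("LaurentPolynomial2", "numeric"),
  function(e1, e2) .lp2Wrap(.lp2_pow(.lp2Raw(e1), as.integer(e2))))

#' Exact division of Laurent polynomials
#'
#' Divides `A` by `B` in the ring of integer Laurent polynomials; raises an
#' internal error unless the division is exact.
#'
#' @param A,B [LaurentPolynomial2-class] objects.
#' @return The exact quotient.
#' @export
laurentDivExact <- function(A, B) {
  out <- tryCatch(.lp2_divexact(.lp2Raw(A), .lp2Raw(B)),
                  error = function(e) .stopInternal(
                    "exact Laurent division failed: %s", conditionMessage(e)))
  .lp2Wrap(out)
}

#' @describeIn laurentPolynomial Coefficient of v^vexp z^zexp, as a decimal
#'   string (vectorized over the exponent pairs).
#' @param P a LaurentPolynomial2.
#' @export
coefficientAt <- function(P, vexp, zexp) {
  as.character(.lp2_coeff(.lp2Raw(P), as.integer(vexp), as.integer(zexp)))
}

#' @describeIn laurentPolynomial v-span: `c(min, max)` of the v-degrees
#'   over all nonzero terms.
#' @export
spanV <- function(P) {
  if (.lp2ZeroQ(P)) .stopPrecondition("the zero polynomial has no v-span")
  c(min(P@vexp), max(P@vexp))
}

#' Mirror image of a link polynomial
#'
#' Applies v -> -1/v, turning the Homfly polynomial of an all-negative link
#' into that of the corresponding all-positive link and vice versa (an
#' involution).
#'
#' @param P a [LaurentPolynomial2-class].
#' @return A [LaurentPolynomial2-class].
#' @export
mirrorLink <- function(P) .lp2Wrap(.lp2_mirror(.lp2Raw(P)))

.lp2FormatTerm <- function(coef, vexp, zexp, var1 = "v", var2 = "z") {
  mono <- c(
    if (vexp != 0L) sprintf(if (vexp == 1L) "%s" else "%s^%d", var1, vexp),
    if (zexp != 0L) sprintf(if (zexp == 1L) "%s" else "%s^%d", var2, zexp))
  mono <- paste(mono, collapse = "*")
  if (!nzchar(mono)) return(coef)
  if (coef == "1") mono
  else if (coef == "-1") paste0("-", mono)
  else paste0(coef, "*", mono)
}

#' Plain-text rendering of a Laurent polynomial
#'
#' Terms in descending z- then v-degree, the order used in the link
#' polynomial literature.
#'
#' @param P a [LaurentPolynomial2-class].
#' @param max.terms truncate the rendering after this many terms.
#' @return A character string.
#' @export
formatLaurent <- function(P, max.terms = Inf) {
  if (.lp2ZeroQ(P)) return("0")
  n <- min(length(P@coef), max.terms)
  parts <- vapply(seq_len(n), function(i)
    .lp2FormatTerm(P@coef[i], P@vexp[i], P@zexp[i]), character(1))
  out <- paste0(parts[1],
    paste0(vapply(parts[-1], function(s) {
      if (startsWith(s, "-")) paste0(" - ", substring(s, 2))
      else paste0(" + ", s)
    }, character(1)), collapse = ""))
  if (n < length(P@coef)) out <- paste0(out, " + ...")
  out
}

setMethod("show", "LaurentPolynomial2", function(object) {
  cat(sprintf("LaurentPolynomial2: %d terms\n", length(object@coef)))
  if (length(object@coef))
    cat(" ", formatLaurent(object, max.terms = 8), "\n")
})

.joinSigned <- function(parts, truncated = FALSE) {
  out <- paste0(parts[1],
    paste0(vapply(parts[-1], function(s) {
      if (startsWith(s, "-")) paste0(" - ", substring(s, 2))
      else paste0(" + ", s)
    }, character(1)), collapse = ""))
  if (truncated) out <- paste0(out, " + ...")
  out
}

setMethod("show", "ConwayPolynomial", function(object) {
  if (!length(object@coef)) {
    cat("ConwayPolynomial: 0\n")
    return(invisible(NULL))
  }
  parts <- vapply(seq_along(object@coef), function(i)
    .lp2FormatTerm(object@coef[i], 0L, object@zexp[i], var2 = "z"),
    character(1))
  cat("ConwayPolynomial:", .joinSigned(parts), "\n")
})

setMethod("show", "JonesPolynomial", function(object) {
  if (!length(object@coef)) {
    cat("JonesPolynomial: 0\n")
    return(invisible(NULL))
  }
  n <- min(length(object@coef), 8L)
  parts <- vapply(seq_len(n), function(i) {
    s <- object@sexp[i]
    mono <- if (s == 0L) "" else if (s %% 2L == 0L)
      sprintf("t^%d", s %/% 2L) else sprintf("t^(%d/2)", s)
    if (!nzchar(mono)) object@coef[i]
    else if (object@coef[i] == "1") mono
    else if (object@coef[i] == "-1") paste0("-", mono)
    else paste0(object@coef[i], "*", mono)
  }, character(1))
  cat("JonesPolynomial:",
      .joinSigned(parts, truncated = length(object@coef) > n), "\n")
})
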