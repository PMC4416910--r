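#' Construct an omega-polynomial
#'
#' @param coef numeric coefficient vector, constant term first.
#' @return An [OmegaPolynomial-class].
#' @examples
#' omegaPolynomial(c(0, 1, 1))  # w + w^2
#' @export
omegaPolynomial <- function(coef = numeric(0)) {
  new("OmegaPolynomial", coef = .omCheck(.omTrim(as.numeric(coef))))
}

#' @describeIn omegaPolynomial Coefficient vector (constant term first).
#' @param x an OmegaPolynomial.
#' @export
omegaCoef <- function(x) x@coef

setMethod("show", "OmegaPolynomial", function(object) {
  cat("OmegaPolynomial:", .omFormat(object@coef), "\n")
})
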