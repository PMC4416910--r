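# Internal arithmetic for polynomials in the flow variable omega.
#
# An omega-polynomial is a plain numeric vector c(c0, c1, c2, ...) holding
# the coefficient of omega^0, omega^1, ... with no trailing zeros; numeric(0)
# is the zero polynomial.  Coefficients are integers held in doubles; every
# operation asserts that they stay strictly below 2^53, so the arithmetic is
# exact.

.OM_MAX <- 2^53

.omCheck <- function(x) {
  if (length(x) && max(abs(x)) >= .OM_MAX)
    .stopInternal("omega-polynomial coefficient overflow beyond 2^53")
  x
}

.omTrim <- function(x) {
  n <- length(x)
  while (n > 0L && x[n] == 0) n <- n - 1L
  if (n == length(x)) x else x[seq_len(n)]
}

.omZero <- numeric(0)
.omOne <- 1
.omOmega <- c(0, 1)

.omIsZero <- function(x) length(x) == 0L

.omAdd <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(.omZero)
  length(a) <- n
  length(b) <- n
  a[is.na(a)] <- 0
  b[is.na(b)] <- 0
  .omCheck(.omTrim(a + b))
}

.omNeg <- function(a) -a

.omScale <- function(a, k) .omCheck(.omTrim(a * k))

.omMul <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(.omZero)
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    if (a[i] != 0)
      out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  .omCheck(.omTrim(out))
}

.omPow <- function(a, k) {
  out <- .omOne
  for (i in seq_len(k)) out <- .omMul(out, a)
  out
}

# value of the polynomial at a numeric omega (exact for small integers)
.omEval <- function(a, w) {
  if (length(a) == 0L) return(0)
  sum(a * w^(seq_along(a) - 1L))
}

.omFormat <- function(a) {
  if (length(a) == 0L) return("0")
  parts <- character(0)
  for (i in seq_along(a)) {
    c0 <- a[i]
    if (c0 == 0) next
    pow <- i - 1L
    base <- if (pow == 0L) "" else if (pow == 1L) "w" else sprintf("w^%d", pow)
    coefTxt <- if (base == "") format(abs(c0), scientific = FALSE)
      else if (abs(c0) == 1) base
      else paste0(format(abs(c0), scientific = FALSE), "*", base)
    sgn <- if (c0 < 0) "-" else "+"
    parts <- c(parts, sgn, coefTxt)
  }
  if (parts[1] == "+") parts <- parts[-1] else parts[1] <- "-"
  paste(parts, collapse = " ")
}
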