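# Published reference polynomials used as frozen expected values, plus a
# small independent expander for the factored two-label forms (kept free of
# the package's own bivariate helpers on purpose).

# ---- chain polynomials ---------------------------------------------------

chThetaExpected <- function() {
  chTermMap(
    list(c("a1", "a2", "a3"), "a1", "a2", "a3", character(0)),
    list(1, c(0, -1), c(0, -1), c(0, -1), c(0, 1, 1)))
}

chK4Expected <- function() {
  singles <- paste0("a", 1:6)
  sets <- c(
    list(singles),
    list(c("a1", "a2", "a3"), c("a1", "a5", "a6"),
         c("a2", "a4", "a6"), c("a3", "a4", "a5"),
         c("a1", "a4"), c("a2", "a5"), c("a3", "a6")),
    as.list(singles),
    list(character(0)))
  coefs <- c(
    list(1),
    rep(list(c(0, -1)), 7),
    rep(list(c(0, 1, 1)), 6),
    list(c(0, -2, -3, -1)))          # -w(w+1)(w+2)
  chTermMap(sets, coefs)
}

# ---- factored two-label forms (expanded independently) -------------------

# dense (b, w) matrix arithmetic: M[i, j] = coefficient of b^(i-1) w^(j-1)
.bwMul <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B) - 1L, ncol(A) + ncol(B) - 1L)
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (A[i, j] == 0) next
    out[i:(i + nrow(B) - 1L), j:(j + ncol(B) - 1L)] <-
      out[i:(i + nrow(B) - 1L), j:(j + ncol(B) - 1L)] + A[i, j] * B
  }
  out
}

.bwPow <- function(A, k) {
  out <- matrix(1, 1, 1)
  for (i in seq_len(k)) out <- .bwMul(out, A)
  out
}

.bwB3 <- rbind(c(0, -1), c(0, 0), c(0, 0), c(1, 0))    # b^3 - w
.bwB2 <- rbind(c(-1, -1), c(1, 0), c(1, 0))            # b^2 + b - w - 1
.bwLin <- rbind(c(-2, -1), c(3, 0))                    # 3b - w - 2

# records: list(coefW, aexp, p, q, r); returns "aexp:bexp" -> omega vector
expandFactoredReference <- function(records) {
  out <- list()
  for (rec in records) {
    M <- .bwMul(.bwPow(.bwB3, rec$p), .bwPow(.bwB2, rec$q))
    M <- .bwMul(M, .bwPow(.bwLin, rec$r))
    cw <- matrix(0, 1, length(rec$coefW))
    cw[1, ] <- rec$coefW
    M <- .bwMul(M, cw)
    for (i in seq_len(nrow(M))) {
      vec <- M[i, ]
      while (length(vec) && vec[length(vec)] == 0)
        vec <- vec[-length(vec)]
      if (!length(vec)) next
      key <- sprintf("%d:%d", rec$aexp, i - 1L)
      cur <- out[[key]]
      out[[key]] <- if (is.null(cur)) vec else {
        n <- max(length(cur), length(vec))
        length(cur) <- n; length(vec) <- n
        cur[is.na(cur)] <- 0; vec[is.na(vec)] <- 0
        s <- cur + vec
        while (length(s) && s[length(s)] == 0) s <- s[-length(s)]
        s
      }
    }
  }
  out <- out[vapply(out, length, integer(1)) > 0L]
  out[sort(names(out), method = "radix")]
}

chThetaPrimeFactored <- function() list(
  list(coefW = 1, aexp = 3L, p = 2L, q = 0L, r = 0L),
  list(coefW = c(0, -3), aexp = 1L, p = 0L, q = 2L, r = 0L),
  list(coefW = c(0, 1, 1), aexp = 0L, p = 0L, q = 0L, r = 2L))

chTPrimeFactored <- function() list(
  list(coefW = 1, aexp = 6L, p = 4L, q = 0L, r = 0L),
  list(coefW = c(0, -4), aexp = 3L, p = 1L, q = 3L, r = 0L),
  list(coefW = c(0, -3), aexp = 2L, p = 0L, q = 4L, r = 0L),
  list(coefW = c(0, 6, 6), aexp = 1L, p = 0L, q = 2L, r = 2L),
  list(coefW = c(0, -2, -3, -1), aexp = 0L, p = 0L, q = 0L, r = 4L))

chHPrimeFactored <- function() list(
  list(coefW = 1, aexp = 12L, p = 8L, q = 0L, r = 0L),
  list(coefW = c(0, -11, -25, -20, -7, -1), aexp = 0L, p = 0L, q = 0L, r = 8L),
  list(coefW = c(0, 48, 96, 60, 12), aexp = 1L, p = 0L, q = 2L, r = 6L),
  list(coefW = c(0, -66, -108, -42), aexp = 2L, p = 0L, q = 4L, r = 4L),
  list(coefW = c(0, -16, -24, -8), aexp = 3L, p = 1L, q = 3L, r = 4L),
  list(coefW = c(0, 32, 32), aexp = 3L, p = 0L, q = 6L, r = 2L),
  list(coefW = c(0, 24, 24), aexp = 4L, p = 1L, q = 5L, r = 2L),
  list(coefW = c(0, -6, 3), aexp = 4L, p = 0L, q = 8L, r = 0L),
  list(coefW = c(0, 12, 12), aexp = 5L, p = 2L, q = 4L, r = 2L),
  list(coefW = c(0, -16), aexp = 6L, p = 2L, q = 6L, r = 0L),
  list(coefW = c(0, -6), aexp = 8L, p = 4L, q = 4L, r = 0L))

# ---- Homfly polynomial of the theta-graph link (all 94 printed terms) ----
# stored as the bracket of  -v^-55 z^-7 ( ... )

homflyThetaBracket <- function() {
  rows <- list(
    c(14, 48, 1), c(14, 46, 7), c(14, 44, 28), c(14, 42, 84), c(14, 40, 207),
    c(14, 38, 441), c(14, 36, 838), c(14, 34, 1450), c(14, 32, 2308),
    c(14, 30, 3388), c(14, 28, 4570), c(14, 26, 5590), c(14, 24, 6069),
    c(14, 22, 5619), c(14, 20, 4116), c(14, 18, 2140), c(14, 16, 679),
    c(14, 14, 97),
    c(12, 42, 3), c(12, 40, 15), c(12, 38, 47), c(12, 36, 115),
    c(12, 34, 246), c(12, 32, 478), c(12, 30, 836), c(12, 28, 1332),
    c(12, 26, 1834), c(12, 24, 2066), c(12, 22, 1554), c(12, 20, -374),
    c(12, 18, -2815), c(12, 16, -3291), c(12, 14, -1705), c(12, 12, -341),
    c(10, 36, 3), c(10, 34, 9), c(10, 32, 36), c(10, 30, 84), c(10, 28, 196),
    c(10, 26, 372), c(10, 24, 528), c(10, 22, 664), c(10, 20, -285),
    c(10, 18, -2319), c(10, 16, -1996), c(10, 14, 684), c(10, 12, 1518),
    c(10, 10, 506),
    c(8, 30, 4), c(8, 28, 4), c(8, 26, 52), c(8, 24, 52), c(8, 22, 238),
    c(8, 20, 238), c(8, 18, -1066), c(8, 16, -1066), c(8, 14, 1190),
    c(8, 12, 1190), c(8, 10, -418), c(8, 8, -418),
    c(6, 24, 9), c(6, 22, -9), c(6, 20, 184), c(6, 18, -184), c(6, 16, -606),
    c(6, 14, 606), c(6, 12, 624), c(6, 10, -624), c(6, 8, -211), c(6, 6, 211),
    c(4, 18, 66), c(4, 16, -198), c(4, 14, 66), c(4, 12, 330), c(4, 10, -330),
    c(4, 8, -66), c(4, 6, 198), c(4, 4, -66),
    c(2, 16, 12), c(2, 14, -60), c(2, 12, 108), c(2, 10, -60), c(2, 8, -60),
    c(2, 6, 108), c(2, 4, -60), c(2, 2, 12),
    c(0, 14, 1), c(0, 12, -7), c(0, 10, 21), c(0, 8, -35), c(0, 6, 35),
    c(0, 4, -21), c(0, 2, 7), c(0, 0, -1))
  mat <- do.call(rbind, rows)
  list(zexp = mat[, 1], vexp = mat[, 2], coef = mat[, 3])
}

homflyThetaExpected <- function() {
  br <- homflyThetaBracket()
  bracket <- laurentPolynomial(br$vexp, br$zexp, br$coef)
  laurentPolynomial(-55L, -7L, -1) * bracket
}

# ---- Jones polynomial of the theta-graph link ----------------------------
# bracket of  -t^(-103/2) ( c48 t^48 + ... + c0 ), coefficients for
# t^48 down to t^0

jonesThetaBracketCoefs <- function() {
  c(1, -7, 28, -84, 210, -462, 924, -1713, 2985, -4939, 7819, -11912,
    17544, -25072, 34875, -47326, 62766, -81462, 103570, -129055, 157634,
    -188690, 221242, -253870, 284755, -311685, 332298, -344228, 345601,
    -335293, 313457, -281464, 242045, -198659, 155160, -114883, 80386,
    -52914, 32652, -18771, 10012, -4907, 2200, -885, 320, -98, 27, -5, 1)
}

# expected (sexp, coef-string) pairs, descending sexp
jonesThetaExpected <- function() {
  cf <- jonesThetaBracketCoefs()
  tpow <- 48:0
  sexp <- 2L * tpow - 103L
  list(sexp = sexp, coef = sprintf("%d", -cf))
}

# ---- printed single-term Conway polynomials ------------------------------

conwayExpected <- function() list(
  theta = list(zexp = 7L, coef = "-37632"),
  tetrahedron = list(zexp = 13L, coef = "-1078984704"),
  cube = list(zexp = 25L, coef = "-748419423085264896"))
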