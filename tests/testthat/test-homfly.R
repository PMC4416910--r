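test_that("theta Homfly polynomial matches the full published polynomial", {
  P <- cachedHomfly("theta")
  expect_true(lpEqual(P, homflyThetaExpected()))
  expect_equal(coefficientAt(P, -31L, 7L), "-6069")
  expect_equal(unname(diff(spanV(P))), 48L)
})

test_that("theta Jones polynomial matches the full published polynomial", {
  J <- jones(cachedHomfly("theta"))
  ref <- jonesThetaExpected()
  expect_identical(J@sexp, as.integer(ref$sexp))
  expect_identical(J@coef, ref$coef)
})

test_that("Conway polynomials of the three links are the printed monomials", {
  ref <- conwayExpected()
  for (nm in names(ref)) {
    cw <- conway(cachedHomfly(nm))
    expect_identical(cw@zexp, ref[[nm]]$zexp, label = nm)
    expect_identical(cw@coef, ref[[nm]]$coef, label = nm)
  }
})

test_that("published Homfly and Jones spot-checks for K4 and the cube", {
  PT <- cachedHomfly("tetrahedron")
  expect_equal(coefficientAt(PT, -25L, 13L), "-18014")
  expect_equal(unname(diff(spanV(PT))), 96L)
  expect_equal(jonesCoefficient(jones(PT), -121L), "-405708071163")

  PH <- cachedHomfly("cube")
  expect_equal(coefficientAt(PH, -39L, 25L), "-2594275")
  expect_equal(unname(diff(spanV(PH))), 192L)
  expect_equal(jonesCoefficient(jones(PH), -389L), "-1083862665")
})

test_that("mirror transform is an involution and commutes with Jones", {
  P <- cachedHomfly("theta")
  expect_true(lpEqual(mirrorLink(mirrorLink(P)), P))
  expect_true(lpEqual(homflyDoubleCrossover(builtinGraph("theta"), "positive"),
                      mirrorLink(P)))
  # jones(mirror(P)) is jones(P) with t -> 1/t
  Jm <- jones(mirrorLink(P))
  J <- jones(P)
  expect_identical(Jm@sexp, rev(-J@sexp))
  expect_identical(Jm@coef, rev(J@coef))
  # Conway of the mirror keeps the magnitude of the single term
  cm <- conway(mirrorLink(P))
  expect_identical(cm@zexp, 7L)
  expect_true(cm@coef %in% c("37632", "-37632"))
})

test_that("the rational substitution cancels exactly on random fixtures", {
  # the pipeline asserts exact divisibility internally, so running it at
  # all is the cancellation check; also assert basic output sanity
  fixtures <- list(loopFreeCubic(2, 1), loopFreeCubic(4, 1),
                   loopFreeCubic(4, 30), loopFreeCubic(6, 1),
                   loopFreeCubic(6, 20))
  for (G in fixtures) {
    P <- homflyDoubleCrossover(G)
    expect_gt(length(P@coef), 0L)
    cw <- conway(P)
    # lowest-degree Conway coefficient is a nonzero integer
    expect_false(cw@coef[length(cw@coef)] == "0")
    b <- braidIndexBounds(P, diagramCrossingNumber(G))
    expect_equal(b@mfwLower, (spanV(P)[2] - spanV(P)[1]) %/% 2L + 1L)
  }
})

test_that("tangle invariants satisfy their defining identities", {
  lp <- laurentPolynomial
  TI <- tangleInvariants()
  delta <- tangleValue(TI, "delta")
  one <- dxlink:::.ratFrom(lp(0L, 0L, 1))

  # printed closed forms
  expect_true(rationalEqual(tangleValue(TI, "nuT2"), one))
  expect_true(rationalEqual(
    tangleValue(TI, "muT1"),
    dxlink:::.ratFrom(lp(c(-2L, -4L, -6L), c(2L, 2L, 2L), c(1, 2, 1)))))
  expect_true(rationalEqual(
    tangleValue(TI, "muT2"),
    dxlink:::.ratFrom(lp(c(-1L, -3L), c(1L, 1L), c(-1, -1)))))
  expect_true(rationalEqual(
    tangleValue(TI, "wT1"),
    methods::new("RationalLaurent",
                 num = lp(c(-3L, -1L, 1L, -1L), c(0L, 0L, 2L, 2L),
                          c(1, -1, -2, -2)),
                 den = lp(c(0L, 2L, 4L), c(3L, 3L, 3L), c(1, 2, 1)))))
  expect_true(rationalEqual(
    tangleValue(TI, "wT2"),
    methods::new("RationalLaurent",
                 num = lp(0L, 0L, -1),
                 den = lp(c(1L, 3L), c(1L, 1L), c(1, 1)))))

  # w(T) (delta Nu - De) = delta De - Nu, for both tangles
  for (tg in c("T1", "T2")) {
    nu <- tangleValue(TI, paste0("nu", tg))
    de <- tangleValue(TI, paste0("de", tg))
    w <- tangleValue(TI, paste0("w", tg))
    lhs <- dxlink:::.ratMul(w, dxlink:::.ratSub(dxlink:::.ratMul(delta, nu), de))
    rhs <- dxlink:::.ratSub(dxlink:::.ratMul(delta, de), nu)
    expect_true(rationalEqual(lhs, rhs), label = tg)
    # mu(T) = (delta Nu - De) / (delta^2 - 1)
    mu <- tangleValue(TI, paste0("mu", tg))
    d2m1 <- dxlink:::.ratSub(dxlink:::.ratMul(delta, delta), one)
    expect_true(rationalEqual(dxlink:::.ratMul(mu, d2m1),
                              dxlink:::.ratSub(dxlink:::.ratMul(delta, nu), de)))
  }
})

test_that("crossing numbers and braid-index bounds match the construction", {
  expect_equal(diagramCrossingNumber(builtinGraph("theta")), 48L)
  expect_equal(diagramCrossingNumber(builtinGraph("tetrahedron")), 96L)
  expect_equal(diagramCrossingNumber(builtinGraph("cube")), 192L)
  expect_error(diagramCrossingNumber(pathGraph(2)),
               class = "dxlinkPreconditionError")

  b <- braidIndexBounds(cachedHomfly("theta"), 48L)
  expect_equal(b@exact, 25L)
  expect_error(braidIndexBounds(cachedHomfly("theta"), 47L), "even",
               class = "dxlinkPreconditionError")
  # odd v-span is rejected
  odd <- laurentPolynomial(c(0L, 1L), c(0L, 0L), c(1, 1))
  expect_error(braidIndexBounds(odd, 4L), "odd",
               class = "dxlinkPreconditionError")
  expect_error(spanV(laurentPolynomial()), class = "dxlinkPreconditionError")
})

test_that("Laurent arithmetic is exact at and beyond 2^53", {
  big <- "123456789012345678901234567890"
  A <- laurentPolynomial(0L, 0L, big)
  B <- A * A
  expect_equal(coefficientAt(B, 0L, 0L),
               "15241578753238836750495351562536198787501905199875019052100")
  expect_true(lpEqual(laurentDivExact(B, A), A))
  expect_error(laurentDivExact(laurentPolynomial(0L, 0L, "7"),
                               laurentPolynomial(0L, 0L, "2")),
               class = "dxlinkInternalError")
})
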