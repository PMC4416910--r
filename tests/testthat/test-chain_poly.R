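test_that("flow polynomial matches the printed and enumerated values", {
  expect_equal(omegaCoef(flowPolynomial(builtinGraph("theta"))), c(0, 1, 1))
  expect_equal(omegaCoef(flowPolynomial(pathGraph(3))), numeric(0))
  expect_equal(omegaCoef(flowPolynomial(loopGraph())), c(0, -1))
  # cube: the omega factor of the constant term of Ch(H')
  expect_equal(omegaCoef(flowPolynomial(builtinGraph("cube"))),
               c(0, -11, -25, -20, -7, -1))
  # K4: -w(w+1)(w+2), the constant term of the printed Ch(T)
  expect_equal(omegaCoef(flowPolynomial(builtinGraph("tetrahedron"))),
               c(0, -2, -3, -1))
})

test_that("flow polynomial agrees with nowhere-zero Z_k flow counts", {
  fixtures <- c(list(builtinGraph("theta"), triangleGraph(), loopGraph()),
                lapply(1:6, function(s) randomCubicMultigraph(4, s)))
  for (G in fixtures) {
    F <- omegaCoef(flowPolynomial(G))
    for (k in 2:4) {
      # F is the flow polynomial at t = 1 - w, so t = k means w = 1 - k
      expect_equal(dxlink:::.omEval(F, 1 - k), countFlowsZk(G, k),
                   label = sprintf("k = %d", k))
    }
  }
})

test_that("chain polynomial reproduces the printed examples", {
  expect_identical(chainTerms(chainPolynomial(builtinGraph("theta"))),
                   chThetaExpected())
  expect_identical(chainTerms(chainPolynomial(builtinGraph("tetrahedron"))),
                   chK4Expected())
  expect_identical(chainTerms(chainPolynomial(loopGraph("a"))),
                   chTermMap(list("a", character(0)), list(1, c(0, -1))))
  expect_identical(chainTerms(chainPolynomial(triangleGraph())),
                   chTermMap(list(c("x", "y", "z"), character(0)),
                             list(1, c(0, -1))))
})

test_that("deletion-contraction equals the subset-sum definition", {
  fixtures <- c(
    list(builtinGraph("theta"), triangleGraph(), pathGraph(3),
         builtinGraph("tetrahedron")),
    lapply(1:10, function(s) randomCubicMultigraph(4, s)),
    lapply(11:14, function(s) randomCubicMultigraph(2, s)))
  for (G in fixtures) {
    expect_identical(chainTerms(chainPolynomial(G)), chainBruteForce(G))
  }
})

test_that("deletion-contraction identities of the chain polynomial hold", {
  fixtures <- lapply(1:10, function(s) randomCubicMultigraph(4, s))
  for (G in fixtures) {
    P <- chainPolynomial(G)
    # constant term = flow polynomial
    const <- chainTerms(P)[[dxlink:::.KEMPTY]]
    if (is.null(const)) const <- numeric(0)
    expect_equal(const, omegaCoef(flowPolynomial(G)))
    # multilinearity
    for (nm in names(chainTerms(P)))
      expect_false(anyDuplicated(dxlink:::.keySplit(nm)) > 0)
    e <- edgeTable(G)
    nonloop <- which(e$u != e$v)
    for (i in nonloop[seq_len(min(3L, length(nonloop)))]) {
      a <- e$label[i]
      H <- labeledMultigraph(G@vertices, e[-i, , drop = FALSE])
      eK <- e[-i, , drop = FALSE]
      eK$u[eK$u == e$v[i]] <- e$u[i]
      eK$v[eK$v == e$v[i]] <- e$u[i]
      K <- labeledMultigraph(setdiff(G@vertices, e$v[i]), eK)
      # coefficient of a is Ch(G - a); setting a = 1 gives Ch(G / a)
      expect_identical(chainCoeffOfLabel(P, a),
                       chainTerms(chainPolynomial(H)))
      expect_identical(chainSetLabelOne(P, a),
                       chainTerms(chainPolynomial(K)))
    }
  }
})

test_that("cut-set terms with all but one edge have zero coefficient", {
  fixtures <- lapply(1:10, function(s) randomCubicMultigraph(4, s))
  for (G in fixtures) {
    P <- chainPolynomial(G)
    e <- edgeTable(G)
    for (j in G@vertices) {
      star <- e$label[(e$u == j) != (e$v == j)]   # incident non-loop edges
      if (length(star) != 3L) next                # loop at j: not a 3-cut
      for (nm in names(chainTerms(P))) {
        hits <- sum(dxlink:::.keySplit(nm) %in% star)
        expect_false(hits == 2L,
                     label = sprintf("vertex %d cut-set in term %s", j, nm))
      }
    }
  }
})

test_that("chain replacement follows the Lemma-1 substitution and inverts", {
  th <- chainPolynomial(builtinGraph("theta"))
  # identity replacement
  expect_identical(chainReplace(th, "a1", "a1")@terms, th@terms)
  # collision is an error unless merging is requested
  expect_error(chainReplace(th, "a1", c("a2", "c")),
               class = "dxlinkPreconditionError")

  # the merged Example-1 substitution: every a_k -> b1 a b2
  P <- th
  for (ak in c("a1", "a2", "a3"))
    P <- chainReplace(P, ak, c("b1", "a", "b2"), allowMerge = TRUE)
  expect_identical(chainTerms(P), chTermMap(
    list(rep(c("a", "b1", "b2"), each = 3), c("a", "b1", "b2"), character(0)),
    list(1, c(0, -3), c(0, 1, 1))))

  # fresh-chain round trip on Ch(T)
  t4 <- chainPolynomial(builtinGraph("tetrahedron"))
  ex <- chainReplace(t4, "a1", c("c1", "c2", "c3"))
  back <- chainCollapse(ex, c("c1", "c2", "c3"), "a1")
  expect_identical(back@terms, t4@terms)
  expect_identical(sort(back@labels), sort(t4@labels))
})

test_that("the Y-delta transform matches Lemma 2 and validates its input", {
  k13 <- labeledMultigraph(0:3, edgeDf(c(0, 0, 0), 1:3, c("x", "y", "z")))
  expect_identical(yDelta(chainPolynomial(k13), "x", "y", "z")@terms,
                   chainPolynomial(triangleGraph())@terms)

  # constant-only polynomial: V -> V (x + y + z - w - 2)
  V <- dxlink:::.newChain(chTermMap(list(character(0)), list(c(5))),
                          labels = character(0))
  expect_identical(yDelta(V, "x", "y", "z")@terms,
                   chTermMap(list("x", "y", "z", character(0)),
                             list(5, 5, 5, c(-10, -5))))

  # a two-of-three cross term violates the cut-set decomposition
  bad <- dxlink:::.newChain(chTermMap(list(c("x", "y")), list(1)),
                            labels = c("x", "y", "z"))
  expect_error(yDelta(bad, "x", "y", "z"), class = "dxlinkInternalError")

  # double Y-delta on the merged theta route reproduces the truncation
  P <- chainPolynomial(builtinGraph("theta"))
  for (ak in c("a1", "a2", "a3"))
    P <- chainReplace(P, ak, c("b1", "a", "b2"), allowMerge = TRUE)
  P <- yDelta(P, "b1", "b1", "b1")
  P <- yDelta(P, "b2", "b2", "b2")
  viaLemmas <- collapseToTwoLabel(P, "a", c("b1", "b2"), n = 2, m = 3)
  expect_identical(twoLabelTerms(viaLemmas),
                   twoLabelTerms(truncateChain(builtinGraph("theta"))))
})
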