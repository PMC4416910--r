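# Theorem-1 engine: the two-label chain polynomial of a truncated cubic
# graph, computed from the chain polynomial of the original graph by
# substitution (never by expanding the truncated graph itself).

# ---- bivariate (b, omega) helpers ----------------------------------------
# a (b, omega)-polynomial is a list indexed by b-exponent + 1, each element
# an omega-coefficient vector (possibly numeric(0))

.bvOne <- list(1)

.bvTrim <- function(A) {
  n <- length(A)
  while (n > 0L && length(A[[n]]) == 0L) n <- n - 1L
  A[seq_len(n)]
}

.bvMul <- function(A, B) {
  if (!length(A) || !length(B)) return(list())
  out <- vector("list", length(A) + length(B) - 1L)
  for (i in seq_along(out)) out[[i]] <- .omZero
  for (i in seq_along(A)) {
    if (!length(A[[i]])) next
    for (j in seq_along(B)) {
      if (!length(B[[j]])) next
      k <- i + j - 1L
      out[[k]] <- .omAdd(out[[k]], .omMul(A[[i]], B[[j]]))
    }
  }
  .bvTrim(out)
}

.bvPow <- function(A, k) {
  out <- .bvOne
  for (i in seq_len(k)) out <- .bvMul(out, A)
  out
}

.bvScale <- function(A, F) {
  .bvTrim(lapply(A, function(x) .omMul(x, F)))
}

# the three omega-b factors of the truncation substitution
.FACTOR_B3 <- list(c(0, -1), .omZero, .omZero, 1)        # b^3 - w
.FACTOR_B2 <- list(c(-1, -1), 1, 1)                      # b^2 + b - w - 1
.FACTOR_LIN <- list(c(-2, -1), 3)                        # 3b - w - 2

.tlKey <- function(aexp, bexp) sprintf("%d:%d", aexp, bexp)

.tlKeyParse <- function(key) as.integer(strsplit(key, ":", fixed = TRUE)[[1]])

# expand a factored term list into an "aexp:bexp" -> omega-vector map
.tlExpand <- function(factored) {
  terms <- list()
  for (rec in factored) {
    prod <- .bvMul(.bvPow(.FACTOR_B3, rec$p), .bvPow(.FACTOR_B2, rec$q))
    prod <- .bvMul(prod, .bvPow(.FACTOR_LIN, rec$r))
    prod <- .bvScale(prod, rec$coef)
    for (i in seq_along(prod)) {
      if (!length(prod[[i]])) next
      key <- .tlKey(rec$aexp, i - 1L)
      cur <- terms[[key]]
      terms[[key]] <- if (is.null(cur)) prod[[i]] else .omAdd(cur, prod[[i]])
    }
  }
  terms <- terms[vapply(terms, length, integer(1)) > 0L]
  if (!length(terms)) return(list())
  terms[sort(names(terms), method = "radix")]
}

.newTwoLabel <- function(factored, n, m, source = "", terms = NULL) {
  expanded <- .tlExpand(factored)
  if (!is.null(terms)) {
    terms <- terms[vapply(terms, length, integer(1)) > 0L]
    terms <- terms[sort(names(terms), method = "radix")]
    if (length(factored) && !identical(terms, expanded))
      .stopInternal("factored and expanded two-label forms disagree")
    expanded <- terms
  }
  new("TwoLabelChainPolynomial", terms = expanded, factored = factored,
      n = as.integer(n), m = as.integer(m), source = as.character(source))
}

# per-term vertex incidence counts q_k for a label subset U of G's edges
.incidenceCounts <- function(G, U) {
  counts <- integer(length(G@vertices))
  sel <- G@edges$label %in% U
  idx <- match(c(G@edges$u[sel], G@edges$v[sel]), G@vertices)
  for (i in idx) counts[i] <- counts[i] + 1L
  counts
}

.checkTruncatePre <- function(G) {
  deg <- .degrees(G)
  if (any(deg != 3L))
    .stopPrecondition("graph is not cubic: vertex %s has degree %d",
                      names(deg)[deg != 3L][1], deg[deg != 3L][1])
  if (any(G@edges$u == G@edges$v))
    .stopPrecondition(
      "graph has a loop (%s): the truncation substitution needs distinct end-vertices",
      G@edges$label[G@edges$u == G@edges$v][1])
}

#' Two-label chain polynomial of the truncated graph, by substitution
#'
#' For a cubic loop-free graph G with n vertices and m edges, computes the
#' chain polynomial of its truncation G' with original-edge images labeled
#' `a` and triangle edges labeled `b`, directly from Ch(G):  every term of
#' Ch(G) with label support U and coefficient F contributes
#' F a^|U| (b^3-w)^p (b^2+b-w-1)^q (3b-w-2)^(n-p-q),
#' where p and q count the vertices of G meeting U in exactly 3 and exactly
#' 1 edges.  A vertex meeting U in exactly 2 edges would contradict the
#' cut-set property of chain polynomials, so that case raises an internal
#' consistency error (it flags a P that is not the chain polynomial of G).
#'
#' @param G a cubic, loop-free [LabeledMultigraph-class].
#' @param P optionally, a precomputed `chainPolynomial(G)`.
#' @param source name recorded in the result (defaults to "").
#' @return A [TwoLabelChainPolynomial-class].
#' @examples
#' truncateChain(builtinGraph("theta"))
#' @export
truncateChain <- function(G, P = NULL, source = "") {
  stopifnot(is(G, "LabeledMultigraph"))
  .checkTruncatePre(G)
  if (is.null(P)) P <- chainPolynomial(G)
  stopifnot(is(P, "ChainPolynomial"))
  if (!setequal(P@labels, G@edges$label))
    .stopPrecondition("P is not a chain polynomial over the edge labels of G")
  n <- nVertices(G)
  m <- nEdges(G)
  factored <- list()
  for (nm in names(P@terms)) {
    U <- .keySplit(nm)
    if (anyDuplicated(U))
      .stopInternal("input polynomial is not multilinear; term [%s]",
                    paste(U, collapse = " "))
    qk <- .incidenceCounts(G, U)
    if (any(qk == 2L))
      .stopInternal(paste0(
        "nonzero term [%s] meets vertex %s in exactly 2 edges; ",
        "P cannot be the chain polynomial of G"),
        paste(U, collapse = " "), G@vertices[qk == 2L][1])
    p <- sum(qk == 3L)
    q <- sum(qk == 1L)
    factored[[length(factored) + 1L]] <- list(
      coef = P@terms[[nm]], aexp = length(U), p = p, q = q, r = n - p - q)
  }
  .newTwoLabel(factored, n = n, m = m, source = source)
}

#' Stepwise truncation substitution
#'
#' Exposes the intermediate polynomials of the substitution:
#' `gstar` is Ch(G*), the chain polynomial after replacing each edge a_k of
#' G by the chain b_i a b_j through its end-vertices (a merged across all
#' edges, one b per vertex), a polynomial in a and b_1..b_n;
#' `gstarstar` is Ch(G**) with b_k^3 replaced by x and b_k by y; `result`
#' is the final two-label polynomial, identical to [truncateChain()].
#'
#' @inheritParams truncateChain
#' @return `list(gstar, gstarstar, result)`.
#' @export
truncateChainStepwise <- function(G, P = NULL, source = "") {
  stopifnot(is(G, "LabeledMultigraph"))
  .checkTruncatePre(G)
  if (is.null(P)) P <- chainPolynomial(G)
  n <- nVertices(G)
  m <- nEdges(G)
  bLab <- paste0("b", G@vertices)
  gstar <- list()
  gstarstar <- list()
  for (nm in names(P@terms)) {
    U <- .keySplit(nm)
    F <- P@terms[[nm]]
    qk <- .incidenceCounts(G, U)
    starKey <- .keyMake(c(rep("a", length(U)),
                          rep(bLab, times = qk)))
    cur <- gstar[[starKey]]
    gstar[[starKey]] <- if (is.null(cur)) F else .omAdd(cur, F)
    if (any(qk == 2L))
      .stopInternal("for nonzero terms in Ch(G*), q_k can not be 2 (term [%s])",
                    paste(U, collapse = " "))
    ssKey <- .keyMake(c(rep("a", length(U)),
                        rep("x", sum(qk == 3L)), rep("y", sum(qk == 1L))))
    cur <- gstarstar[[ssKey]]
    gstarstar[[ssKey]] <- if (is.null(cur)) F else .omAdd(cur, F)
  }
  list(
    gstar = .newChain(gstar, labels = c("a", bLab)),
    gstarstar = .newChain(gstarstar, labels = c("a", "x", "y")),
    result = truncateChain(G, P, source = source)
  )
}

#' Collapse the labels of a chain polynomial to the two truncation labels
#'
#' Substitutes every label in `aLabels` by `a` and every label in `bLabels`
#' by `b`, producing a [TwoLabelChainPolynomial-class] (expanded form only,
#' no factored form).  This is how a direct deletion-contraction chain
#' polynomial of a structurally truncated graph is brought into the shape
#' of the substitution result for comparison.
#'
#' @param P a [ChainPolynomial-class] over `aLabels` and `bLabels`.
#' @param aLabels,bLabels disjoint character vectors covering `P`'s labels.
#' @param n,m vertex and edge counts of the original (untruncated) graph.
#' @param source recorded name.
#' @return A [TwoLabelChainPolynomial-class].
#' @export
collapseToTwoLabel <- function(P, aLabels, bLabels, n, m, source = "") {
  stopifnot(is(P, "ChainPolynomial"))
  if (length(intersect(aLabels, bLabels)))
    .stopPrecondition("aLabels and bLabels overlap")
  extra <- setdiff(P@labels, c(aLabels, bLabels))
  if (length(extra))
    .stopPrecondition("label '%s' is in neither family", extra[1])
  terms <- list()
  for (nm in names(P@terms)) {
    labs <- .keySplit(nm)
    key <- .tlKey(sum(labs %in% aLabels), sum(labs %in% bLabels))
    cur <- terms[[key]]
    terms[[key]] <- if (is.null(cur)) P@terms[[nm]]
      else .omAdd(cur, P@terms[[nm]])
  }
  .newTwoLabel(list(), n = n, m = m, source = source, terms = terms)
}

#' @describeIn truncateChain Expanded term map: named list
#'   `"aexp:bexp" -> omega coefficient vector`.
#' @export
twoLabelTerms <- function(P) P@terms

#' @describeIn truncateChain Factored term records
#'   `list(coef, aexp, p, q, r)`.
#' @export
factoredTerms <- function(P) P@factored

# value at a = b = 1 (omega-polynomial); used by equivalence checks
.twoLabelAtOnes <- function(P) {
  Reduce(.omAdd, P@terms, .omZero)
}

setMethod("show", "TwoLabelChainPolynomial", function(object) {
  cat(sprintf(
    "TwoLabelChainPolynomial%s: %d expanded terms (n = %d, m = %d)\n",
    if (nzchar(object@source)) sprintf(" [%s]", object@source) else "",
    length(object@terms), object@n, object@m))
  if (length(object@factored)) {
    cat("  factored form:\n")
    for (rec in object@factored[seq_len(min(6L, length(object@factored)))])
      cat(sprintf("   (%s) * a^%d * (b^3-w)^%d * (b^2+b-w-1)^%d * (3b-w-2)^%d\n",
                  .omFormat(rec$coef), rec$aexp, rec$p, rec$q, rec$r))
    if (length(object@factored) > 6L)
      cat(sprintf("   ... and %d more factored terms\n",
                  length(object@factored) - 6L))
  }
})
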