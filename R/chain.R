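# Chain and flow polynomials of labeled multigraphs.
#
# Term keys: the labels of a term, sorted bytewise and joined by "\x1f",
# with repeats for labels of exponent > 1 ("" = constant term).

.keySplit <- function(key) {
  if (key == .KEMPTY) character(0)
  else strsplit(key, .SEP, fixed = TRUE)[[1]]
}

.keyMake <- function(labels) {
  if (!length(labels)) .KEMPTY
  else paste(sort(labels, method = "radix"), collapse = .SEP)
}

# ---- term-map helpers (named lists of omega-polynomials) -----------------

.chAdd <- function(A, B) {
  for (nm in names(B)) {
    cur <- A[[nm]]
    A[[nm]] <- if (is.null(cur)) B[[nm]] else .omAdd(cur, B[[nm]])
  }
  A
}

.chDropZero <- function(A) {
  A[vapply(A, length, integer(1)) > 0L]
}

# multiply a term map by (lab - 1): deletion-contraction combination step
.chMulLabelMinus1 <- function(A, lab) {
  out <- list()
  for (nm in names(A)) {
    F <- A[[nm]]
    out[[.keyMake(c(.keySplit(nm), lab))]] <- F
    out[[nm]] <- .omNeg(F)
  }
  out
}

# multiply a term map by (lab - w): chain-polynomial factor of a loop
.chMulLoop <- function(A, lab) {
  out <- list()
  for (nm in names(A)) {
    F <- A[[nm]]
    out[[.keyMake(c(.keySplit(nm), lab))]] <- F
    out[[nm]] <- .omMul(F, c(0, -1))
  }
  out
}

# full product of two term maps (label supports must not be assumed
# disjoint: keys concatenate as multisets)
.chMul <- function(A, B) {
  out <- list()
  for (na in names(A)) {
    la <- .keySplit(na)
    Fa <- A[[na]]
    for (nb in names(B)) {
      key <- .keyMake(c(la, .keySplit(nb)))
      prod <- .omMul(Fa, B[[nb]])
      cur <- out[[key]]
      out[[key]] <- if (is.null(cur)) prod else .omAdd(cur, prod)
    }
  }
  out
}

.chConst <- function() {
  out <- list(.omOne)
  names(out) <- .KEMPTY
  out
}

.newChain <- function(terms, labels) {
  terms <- .chDropZero(terms)
  terms <- terms[sort(names(terms), method = "radix")]
  new("ChainPolynomial", terms = terms,
      labels = sort(unique(labels), method = "radix"))
}

# canonical memo key: edges sorted by label, vertices renamed by first
# appearance in that ordering
.graphKey <- function(u, v, lab) {
  vs <- unique(as.integer(rbind(u, v)))
  paste(match(u, vs), match(v, vs), lab, sep = ",", collapse = ";")
}

.chainRec <- function(u, v, lab, memo) {
  if (length(lab) == 0L) return(.chConst())
  o <- order(lab, method = "radix")
  u <- u[o]; v <- v[o]; lab <- lab[o]
  key <- .graphKey(u, v, lab)
  hit <- get0(key, envir = memo, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  loops <- u == v
  if (any(loops)) {
    res <- .chainRec(u[!loops], v[!loops], lab[!loops], memo)
    for (ll in lab[loops]) res <- .chMulLoop(res, ll)
  } else {
    comp <- .edgeComponents(u, v)
    if (max(comp) > 1L) {
      res <- .chConst()
      for (cid in unique(comp)) {
        sel <- comp == cid
        res <- .chMul(res, .chainRec(u[sel], v[sel], lab[sel], memo))
      }
    } else {
      # pivot on the lexicographically smallest non-loop label (index 1)
      PH <- .chainRec(u[-1], v[-1], lab[-1], memo)
      cu <- u[-1]; cv <- v[-1]
      cu[cu == v[1]] <- u[1]
      cv[cv == v[1]] <- u[1]
      PK <- .chainRec(cu, cv, lab[-1], memo)
      res <- .chAdd(.chMulLabelMinus1(PH, lab[1]), PK)
    }
  }
  res <- .chDropZero(res)
  assign(key, res, envir = memo)
  res
}

#' Chain polynomial of a labeled multigraph
#'
#' Computes the chain polynomial Ch(G): the sum over all edge subsets Y of
#' the flow polynomial (in omega, at 1 - omega) of the spanning subgraph on
#' Y times the product of the labels of the other edges.  The computation
#' uses deletion-contraction, Ch(G) = (a - 1) Ch(G - a) + Ch(G / a), with an
#' edgeless graph giving 1, a loop labeled a giving the factor (a - omega),
#' and multiplicativity over components and cut vertices.  The pivot is
#' always the lexicographically smallest non-loop label, so the recursion
#' tree is reproducible.
#'
#' @param G a [LabeledMultigraph-class]; loops and parallel edges are fine.
#' @return A [ChainPolynomial-class], multilinear in the edge labels.
#' @examples
#' chainPolynomial(builtinGraph("theta"))  # a1 a2 a3 - w(a1+a2+a3) + w^2 + w
#' @export
chainPolynomial <- function(G) {
  stopifnot(is(G, "LabeledMultigraph"))
  memo <- new.env(parent = emptyenv())
  terms <- .chainRec(G@edges$u, G@edges$v, G@edges$label, memo)
  .newChain(terms, labels = G@edges$label)
}

#' @describeIn chainPolynomial The term map of a chain polynomial: a named
#'   list from "\x1f"-joined label keys to omega-coefficient vectors.
#' @param P a ChainPolynomial.
#' @export
chainTerms <- function(P) P@terms

#' @describeIn chainPolynomial The label universe.
#' @export
chainLabels <- function(P) P@labels

#' @describeIn chainPolynomial Coefficient (an [OmegaPolynomial-class]) of
#'   the term with exactly the given labels (with multiplicity).
#' @param labels character vector of labels selecting one term.
#' @export
chainCoefficient <- function(P, labels) {
  F <- P@terms[[.keyMake(labels)]]
  omegaPolynomial(if (is.null(F)) numeric(0) else F)
}

setMethod("show", "ChainPolynomial", function(object) {
  cat(sprintf("ChainPolynomial: %d terms in %d labels\n",
              length(object@terms), length(object@labels)))
  nm <- names(object@terms)
  shown <- min(length(nm), 10L)
  for (i in seq_len(shown)) {
    labs <- .keySplit(nm[i])
    lhs <- if (length(labs)) paste(labs, collapse = "*") else "1"
    cat(sprintf("  [%s] %s\n", lhs, .omFormat(object@terms[[i]])))
  }
  if (length(nm) > shown) cat(sprintf("  ... and %d more terms\n",
                                      length(nm) - shown))
})

# ------------------------------------------------------ flow polynomial --

.flowRec <- function(u, v, lab, memo) {
  if (length(lab) == 0L) return(.omOne)
  o <- order(lab, method = "radix")
  u <- u[o]; v <- v[o]; lab <- lab[o]
  key <- .graphKey(u, v, lab)
  hit <- get0(key, envir = memo, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  loops <- u == v
  if (any(loops)) {
    res <- .flowRec(u[!loops], v[!loops], lab[!loops], memo)
    for (i in seq_len(sum(loops))) res <- .omMul(res, c(0, -1))  # (-w) each
  } else if (any(.findBridges(u, v, unique(c(u, v))))) {
    res <- .omZero
  } else {
    comp <- .edgeComponents(u, v)
    if (max(comp) > 1L) {
      res <- .omOne
      for (cid in unique(comp)) {
        sel <- comp == cid
        res <- .omMul(res, .flowRec(u[sel], v[sel], lab[sel], memo))
        if (.omIsZero(res)) break
      }
    } else {
      cu <- u[-1]; cv <- v[-1]
      cu[cu == v[1]] <- u[1]
      cv[cv == v[1]] <- u[1]
      res <- .omAdd(.flowRec(cu, cv, lab[-1], memo),
                    .omNeg(.flowRec(u[-1], v[-1], lab[-1], memo)))
    }
  }
  assign(key, res, envir = memo)
  res
}

#' Flow polynomial in the omega variable
#'
#' The flow polynomial of G evaluated at t = 1 - omega, the coefficient
#' convention under which the constant term of [chainPolynomial()] equals
#' the flow polynomial.  Zero whenever G has a bridge; a loop contributes a
#' factor -omega; multiplicative over components and blocks.
#'
#' @param G a [LabeledMultigraph-class].
#' @return An [OmegaPolynomial-class].
#' @examples
#' flowPolynomial(builtinGraph("theta"))  # w^2 + w
#' @export
flowPolynomial <- function(G) {
  stopifnot(is(G, "LabeledMultigraph"))
  memo <- new.env(parent = emptyenv())
  omegaPolynomial(.flowRec(G@edges$u, G@edges$v, G@edges$label, memo))
}

# ---------------------------------------------------- label substitution --

#' Replace a label by a chain of labels (and back)
#'
#' `chainReplace()` substitutes `target -> prod(chain)` in every term,
#' mirroring the replacement of an edge by a chain of edges.
#' `chainCollapse()` is the converse: every full occurrence of the chain
#' product is collapsed back to `target`; a term containing only part of
#' the chain is an error (such terms cannot occur for an actual graph
#' chain, whose partial subgraphs have bridges).
#'
#' By default chain labels must be fresh.  Substitutions that deliberately
#' merge labels across edges -- e.g. replacing every edge a_k of the theta
#' graph by b1 * a * b2 with shared symbols, which produces the non-
#' multilinear a^3 b1^3 b2^3 term -- require `allowMerge = TRUE`.
#'
#' @param P a [ChainPolynomial-class].
#' @param target a single label present in `P`.
#' @param chain character vector of replacement labels, in chain order.
#' @param allowMerge permit chain labels that already occur in `P`.
#' @return A [ChainPolynomial-class].
#' @export
chainReplace <- function(P, target, chain, allowMerge = FALSE) {
  stopifnot(is(P, "ChainPolynomial"), length(target) == 1L)
  if (!target %in% P@labels)
    .stopPrecondition("label '%s' does not occur in the polynomial", target)
  if (identical(chain, target)) return(P)
  clash <- intersect(chain, setdiff(P@labels, target))
  if (length(clash) && !allowMerge)
    .stopPrecondition("chain label '%s' collides with an existing label",
                      clash[1])
  out <- list()
  for (nm in names(P@terms)) {
    labs <- .keySplit(nm)
    hits <- labs == target
    newLabs <- c(labs[!hits], rep(chain, sum(hits)))
    key <- .keyMake(newLabs)
    cur <- out[[key]]
    out[[key]] <- if (is.null(cur)) P@terms[[nm]]
      else .omAdd(cur, P@terms[[nm]])
  }
  .newChain(out, labels = c(setdiff(P@labels, target), chain))
}

#' @rdname chainReplace
#' @export
chainCollapse <- function(P, chain, target) {
  stopifnot(is(P, "ChainPolynomial"))
  if (target %in% setdiff(P@labels, chain))
    .stopPrecondition("target label '%s' already exists", target)
  out <- list()
  for (nm in names(P@terms)) {
    labs <- .keySplit(nm)
    counts <- vapply(unique(chain), function(cl) sum(labs == cl), integer(1))
    e <- min(counts)
    if (any(counts != e))
      .stopPrecondition(
        "term contains only part of the chain (%s); cannot collapse",
        paste(chain, collapse = ", "))
    rest <- labs[!labs %in% chain]
    key <- .keyMake(c(rest, rep(target, e)))
    cur <- out[[key]]
    out[[key]] <- if (is.null(cur)) P@terms[[nm]]
      else .omAdd(cur, P@terms[[nm]])
  }
  .newChain(out, labels = c(setdiff(P@labels, chain), target))
}

# -------------------------------------------------------------- Y-delta --

#' The Y-delta transform on a chain polynomial
#'
#' For a graph with a degree-3 vertex whose incident edges carry labels
#' x, y, z, the chain polynomial decomposes exactly as
#' P xyz + A x + B y + C z + V (cut-set terms with two of the three labels
#' have zero coefficient), and the chain polynomial of the Y-delta
#' transformed graph is
#' P (xyz - w) + A (yz + x - w - 1) + B (xz + y - w - 1) +
#' C (xy + z - w - 1) + V (x + y + z - w - 2).
#' The decomposition is validated, so a polynomial that is not of this
#' shape raises a structural error instead of a silent wrong answer.
#' Merged labels (x = y = z) are handled by total exponent, matching the
#' per-vertex substitution used for truncation.
#'
#' @param P a [ChainPolynomial-class].
#' @param x,y,z the labels at the degree-3 vertex (the same names become
#'   the triangle labels).
#' @return A [ChainPolynomial-class].
#' @export
yDelta <- function(P, x, y, z) {
  stopifnot(is(P, "ChainPolynomial"))
  xyz <- c(x, y, z)
  out <- list()
  emit <- function(key, F) {
    if (.omIsZero(F)) return()
    cur <- out[[key]]
    out[[key]] <<- if (is.null(cur)) F else .omAdd(cur, F)
  }
  for (nm in names(P@terms)) {
    labs <- .keySplit(nm)
    inTriple <- labs %in% xyz
    part <- labs[inTriple]
    base <- labs[!inTriple]
    F <- P@terms[[nm]]
    if (length(part) == 0L) {
      # V-part: multiply by (x + y + z - w - 2)
      emit(.keyMake(c(base, x)), F)
      emit(.keyMake(c(base, y)), F)
      emit(.keyMake(c(base, z)), F)
      emit(.keyMake(base), .omMul(F, c(-2, -1)))
    } else if (length(part) == 3L &&
               identical(sort(part, method = "radix"),
                         sort(xyz, method = "radix"))) {
      # full xyz: substitute xyz -> xyz - w
      emit(.keyMake(c(base, xyz)), F)
      emit(.keyMake(base), .omMul(F, c(0, -1)))
    } else if (length(part) == 1L) {
      # single label, say x: substitute x -> yz + x - w - 1
      others <- xyz[-match(part, xyz)]
      emit(.keyMake(c(base, others)), F)
      emit(.keyMake(c(base, part)), F)
      emit(.keyMake(base), .omMul(F, c(-1, -1)))
    } else {
      .stopInternal(paste0(
        "term [%s] carries %d of the three labels {%s}: the cut-set ",
        "decomposition required by the Y-delta theorem fails"),
        paste(labs, collapse = " "), length(part),
        paste(xyz, collapse = ", "))
    }
  }
  .newChain(out, labels = unique(c(P@labels, xyz)))
}
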