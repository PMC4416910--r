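# Shared fixtures and independent oracles.

# term-map builder: chTerms(list(c("a1","a2"), character(0)), list(1, c(0,1)))
chTermMap <- function(labelSets, coefs) {
  out <- list()
  for (i in seq_along(labelSets)) {
    out[[dxlink:::.keyMake(labelSets[[i]])]] <- as.numeric(coefs[[i]])
  }
  out[sort(names(out), method = "radix")]
}

edgeDf <- function(u, v, label) {
  data.frame(u = as.integer(u), v = as.integer(v), label = label,
             stringsAsFactors = FALSE)
}

# one-edge path, triangle, star fixtures
pathGraph <- function(k) {
  labeledMultigraph(0:k, edgeDf(0:(k - 1), 1:k, paste0("p", 1:k)))
}

triangleGraph <- function(labels = c("x", "y", "z")) {
  labeledMultigraph(0:2, edgeDf(c(0, 1, 2), c(1, 2, 0), labels))
}

loopGraph <- function(label = "a") {
  labeledMultigraph(0L, edgeDf(0, 0, label))
}

k33Graph <- function() {
  u <- rep(0:2, each = 3)
  v <- rep(3:5, times = 3)
  labeledMultigraph(0:5, edgeDf(u, v, paste0("e", 1:9)))
}

# loop-free random cubic fixture: first seed >= seedStart whose pairing
# draws no loop (deterministic scan)
loopFreeCubic <- function(nVertices, seedStart) {
  for (s in seedStart + 0:499) {
    g <- randomCubicMultigraph(nVertices, s)
    if (!any(edgeTable(g)$u == edgeTable(g)$v)) return(g)
  }
  stop("no loop-free pairing found")
}

# ---- independent oracles -------------------------------------------------

# Definition-level chain polynomial: sum over all edge subsets Y of
# flow(<Y>) * product of labels outside Y.  Only feasible for small m.
chainBruteForce <- function(G) {
  e <- edgeTable(G)
  m <- nrow(e)
  acc <- list()
  for (mask in 0:(2^m - 1)) {
    inY <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    sub <- labeledMultigraph(G@vertices, e[inY, , drop = FALSE])
    F <- omegaCoef(flowPolynomial(sub))
    if (!length(F)) next
    key <- dxlink:::.keyMake(e$label[!inY])
    cur <- acc[[key]]
    acc[[key]] <- if (is.null(cur)) F else dxlink:::.omAdd(cur, F)
  }
  acc <- acc[vapply(acc, length, integer(1)) > 0L]
  acc[sort(names(acc), method = "radix")]
}

# number of nowhere-zero Z_k flows, by direct enumeration (orient each
# edge u -> v; loops always conserve and contribute a factor k - 1)
countFlowsZk <- function(G, k) {
  e <- edgeTable(G)
  loops <- e$u == e$v
  nLoop <- sum(loops)
  e <- e[!loops, , drop = FALSE]
  m <- nrow(e)
  if (m == 0L) return((k - 1)^nLoop)
  vals <- rep(list(1:(k - 1)), m)
  grid <- as.matrix(expand.grid(vals))
  ok <- 0L
  for (r in seq_len(nrow(grid))) {
    flow <- grid[r, ]
    net <- integer(length(G@vertices))
    for (i in seq_len(m)) {
      ui <- match(e$u[i], G@vertices)
      vi <- match(e$v[i], G@vertices)
      net[ui] <- net[ui] + flow[i]
      net[vi] <- net[vi] - flow[i]
    }
    if (all(net %% k == 0)) ok <- ok + 1L
  }
  ok * (k - 1)^nLoop
}

# evaluate a chain polynomial at label = 1 (contraction identity helper)
chainSetLabelOne <- function(P, lab) {
  out <- list()
  for (nm in names(chainTerms(P))) {
    labs <- dxlink:::.keySplit(nm)
    key <- dxlink:::.keyMake(labs[labs != lab])
    cur <- out[[key]]
    F <- chainTerms(P)[[nm]]
    out[[key]] <- if (is.null(cur)) F else dxlink:::.omAdd(cur, F)
  }
  out <- out[vapply(out, length, integer(1)) > 0L]
  out[sort(names(out), method = "radix")]
}

# coefficient-of-label extraction: terms containing lab, with lab removed
chainCoeffOfLabel <- function(P, lab) {
  out <- list()
  for (nm in names(chainTerms(P))) {
    labs <- dxlink:::.keySplit(nm)
    if (!lab %in% labs) next
    out[[dxlink:::.keyMake(labs[labs != lab])]] <- chainTerms(P)[[nm]]
  }
  out[sort(names(out), method = "radix")]
}

lpEqual <- function(A, B) length((A - B)@coef) == 0L

# session-level cache so the cube Homfly polynomial is computed once
.hfCache <- new.env(parent = emptyenv())
cachedHomfly <- function(name) {
  hit <- get0(name, envir = .hfCache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  P <- homflyDoubleCrossover(builtinGraph(name))
  assign(name, P, envir = .hfCache)
  P
}
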