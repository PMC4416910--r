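#' Construct a labeled multigraph
#'
#' @param vertices integer vector of vertex ids (0-based by convention).
#' @param edges data.frame (or list coercible to one) with columns `u`, `v`,
#'   `label`; or a 3-column list of `list(u, v, label)` triples.
#' @return A [LabeledMultigraph-class] object.
#' @examples
#' theta <- labeledMultigraph(0:1,
#'   data.frame(u = c(0L, 0L, 0L), v = c(1L, 1L, 1L),
#'              label = c("a1", "a2", "a3")))
#' @export
labeledMultigraph <- function(vertices, edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L) ||
      (!is.data.frame(edges) && length(edges) == 0L)) {
    edges <- data.frame(u = integer(0), v = integer(0),
                        label = character(0), stringsAsFactors = FALSE)
  } else if (!is.data.frame(edges)) {
    edges <- data.frame(
      u = vapply(edges, function(e) as.integer(e[[1]]), integer(1)),
      v = vapply(edges, function(e) as.integer(e[[2]]), integer(1)),
      label = vapply(edges, function(e) as.character(e[[3]]), character(1)),
      stringsAsFactors = FALSE)
  }
  edges$u <- as.integer(edges$u)
  edges$v <- as.integer(edges$v)
  edges$label <- as.character(edges$label)
  rownames(edges) <- NULL
  g <- new("LabeledMultigraph", vertices = as.integer(vertices), edges = edges)
  g
}

#' @describeIn labeledMultigraph Number of vertices.
#' @param G a LabeledMultigraph.
#' @export
nVertices <- function(G) length(G@vertices)

#' @describeIn labeledMultigraph Number of edges.
#' @export
nEdges <- function(G) nrow(G@edges)

#' @describeIn labeledMultigraph Edge labels in edge order.
#' @export
edgeLabels <- function(G) G@edges$label

#' @describeIn labeledMultigraph Edge table (columns u, v, label).
#' @export
edgeTable <- function(G) G@edges

setMethod("show", "LabeledMultigraph", function(object) {
  cat(sprintf("LabeledMultigraph: %d vertices, %d edges\n",
              nVertices(object), nEdges(object)))
  e <- object@edges
  n <- min(nrow(e), 12L)
  for (i in seq_len(n))
    cat(sprintf("  %s: (%d, %d)\n", e$label[i], e$u[i], e$v[i]))
  if (nrow(e) > n) cat(sprintf("  ... and %d more edges\n", nrow(e) - n))
})

# ------------------------------------------------------------------- I/O --

#' Read / write the graph JSON dialect
#'
#' The on-disk dialect is
#' `{"vertices":[0,1,...], "edges":[[u,v,"label"],...]}`.
#' `loadGraph()` validates the file and reports the offending record on
#' failure; `saveGraph()` writes a canonical serialization so that
#' load/save round-trips are byte-identical.
#'
#' @param path file path.
#' @return `loadGraph()` a [LabeledMultigraph-class]; `saveGraph()` the path,
#'   invisibly.
#' @export
loadGraph <- function(path) {
  if (!file.exists(path)) .stopFormat("no such file: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) .stopFormat("malformed JSON in %s: %s",
                                                  path, conditionMessage(e)))
  if (!is.list(doc) || is.null(doc$vertices) || is.null(doc$edges))
    .stopFormat("graph JSON must have 'vertices' and 'edges' fields")
  verts <- vapply(doc$vertices, function(x) {
    if (!is.numeric(x) || x != as.integer(x))
      .stopFormat("non-integer vertex id: %s", format(x))
    as.integer(x)
  }, integer(1))
  edges <- lapply(doc$edges, function(e) {
    if (length(e) != 3L)
      .stopFormat("edge record must be [u, v, \"label\"], got length %d",
                  length(e))
    e
  })
  g <- tryCatch(labeledMultigraph(verts, edges),
                error = function(e) .stopFormat("invalid graph in %s: %s",
                                                path, conditionMessage(e)))
  g
}

#' @rdname loadGraph
#' @param G a LabeledMultigraph.
#' @export
saveGraph <- function(G, path) {
  stopifnot(is(G, "LabeledMultigraph"))
  e <- G@edges
  edgeJson <- vapply(seq_len(nrow(e)), function(i) {
    sprintf("[%d,%d,%s]", e$u[i], e$v[i],
            jsonlite::toJSON(e$label[i], auto_unbox = TRUE))
  }, character(1))
  txt <- sprintf('{"vertices":[%s],"edges":[%s]}',
                 paste(G@vertices, collapse = ","),
                 paste(edgeJson, collapse = ","))
  writeLines(txt, path)
  invisible(path)
}

# -------------------------------------------------------------- builtins --

#' Builtin named graphs
#'
#' The labeled graphs used throughout the double-crossover link literature:
#' the theta graph (2 vertices joined by 3 parallel edges a1..a3), the
#' generalized theta `theta_m(m)` (m parallel edges), the tetrahedral graph
#' K4 (labeled a1..a6 so that its four triangles are \{a1,a2,a3\},
#' \{a1,a5,a6\}, \{a2,a4,a6\}, \{a3,a4,a5\}), the hexahedral (cube) graph
#' (a1..a12) and the triangular prism `prism3` (a1..a9).
#'
#' @param name one of `"theta"`, `"theta_m(m)"` (e.g. `"theta_m(5)"`),
#'   `"tetrahedron"`, `"cube"`, `"prism3"`.
#' @return A [LabeledMultigraph-class].
#' @examples
#' builtinGraph("tetrahedron")
#' @export
builtinGraph <- function(name) {
  mTheta <- NULL
  if (grepl("^theta_m\\([0-9]+\\)$", name))
    mTheta <- as.integer(sub("^theta_m\\(([0-9]+)\\)$", "\\1", name))
  if (!is.null(mTheta)) {
    if (mTheta < 1L) .stopUsage("theta_m needs at least one edge")
    return(labeledMultigraph(0:1, data.frame(
      u = rep(0L, mTheta), v = rep(1L, mTheta),
      label = paste0("a", seq_len(mTheta)), stringsAsFactors = FALSE)))
  }
  edges <- switch(name,
    theta = list(
      c(0L, 1L), c(0L, 1L), c(0L, 1L)),
    tetrahedron = list(
      # vertex stars {a1,a2,a3}, {a1,a5,a6}, {a2,a4,a6}, {a3,a4,a5} and
      # perfect-matching pairs a1a4, a2a5, a3a6, matching the printed Ch(T)
      # (whose -w terms are the complements of triangles and 4-cycles)
      c(0L, 1L), c(0L, 2L), c(0L, 3L), c(2L, 3L), c(1L, 3L), c(1L, 2L)),
    cube = list(
      c(0L, 1L), c(1L, 2L), c(2L, 3L), c(3L, 0L),
      c(0L, 4L), c(1L, 5L), c(2L, 6L), c(3L, 7L),
      c(4L, 5L), c(5L, 6L), c(6L, 7L), c(7L, 4L)),
    prism3 = list(
      c(0L, 1L), c(1L, 2L), c(2L, 0L),
      c(0L, 3L), c(1L, 4L), c(2L, 5L),
      c(3L, 4L), c(4L, 5L), c(5L, 3L)),
    .stopUsage(paste0(
      "unknown builtin graph '%s'; valid names: theta, theta_m(m), ",
      "tetrahedron, cube, prism3"), name)
  )
  u <- vapply(edges, `[`, integer(1), 1L)
  v <- vapply(edges, `[`, integer(1), 2L)
  labeledMultigraph(0:max(u, v), data.frame(
    u = u, v = v, label = paste0("a", seq_along(edges)),
    stringsAsFactors = FALSE))
}

#' @rdname builtinGraph
#' @export
builtinGraphNames <- function() {
  c("theta", "theta_m(m)", "tetrahedron", "cube", "prism3")
}

# --------------------------------------------------------- random cubic ---

#' Random cubic multigraph by the pairing model
#'
#' Draws a seeded uniform pairing of the 3n half-edge stubs of n vertices;
#' loops and parallel edges are kept.  Identical seeds give identical
#' graphs; the caller's RNG state is untouched.
#'
#' @param nVertices even vertex count, at least 2.
#' @param seed integer seed.
#' @return A cubic [LabeledMultigraph-class] with edges labeled e1, e2, ...
#' @export
randomCubicMultigraph <- function(nVertices, seed) {
  nVertices <- as.integer(nVertices)
  if (nVertices < 2L || nVertices %% 2L != 0L)
    .stopPrecondition("nVertices must be even and >= 2, got %d", nVertices)
  stubs <- rep(seq_len(nVertices) - 1L, each = 3L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  perm <- sample(length(stubs))
  paired <- stubs[perm]
  m <- length(stubs) / 2L
  u <- paired[2L * seq_len(m) - 1L]
  v <- paired[2L * seq_len(m)]
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  labeledMultigraph(seq_len(nVertices) - 1L, data.frame(
    u = u, v = v, label = paste0("e", seq_len(m)), stringsAsFactors = FALSE))
}

# ----------------------------------------------------------------- stats --

.degrees <- function(G) {
  deg <- integer(length(G@vertices))
  names(deg) <- as.character(G@vertices)
  for (x in c(G@edges$u, G@edges$v)) {
    k <- as.character(x)
    deg[k] <- deg[k] + 1L
  }
  deg
}

.isCubic <- function(G) nVertices(G) > 0L && all(.degrees(G) == 3L)

# Tarjan bridge finding on the multigraph; loops and any member of a
# parallel class are never bridges.  Returns a logical per edge row.
.findBridges <- function(u, v, vertices) {
  m <- length(u)
  out <- logical(m)
  if (m == 0L) return(out)
  idx <- match(c(u, v), vertices)
  eu <- idx[seq_len(m)]
  ev <- idx[m + seq_len(m)]
  nV <- length(vertices)
  adj <- vector("list", nV)
  for (i in seq_len(m)) {
    if (eu[i] == ev[i]) next  # loops never bridges
    adj[[eu[i]]] <- c(adj[[eu[i]]], list(c(ev[i], i)))
    adj[[ev[i]]] <- c(adj[[ev[i]]], list(c(eu[i], i)))
  }
  disc <- integer(nV); low <- integer(nV); timer <- 0L
  # iterative DFS to be safe on long paths
  for (root in seq_len(nV)) {
    if (disc[root] != 0L) next
    stack <- list(list(node = root, parentEdge = 0L, ptr = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      node <- fr$node
      if (fr$ptr == 1L) {
        timer <- timer + 1L
        disc[node] <- low[node] <- timer
      }
      nbrs <- adj[[node]]
      if (fr$ptr <= length(nbrs)) {
        stack[[length(stack)]]$ptr <- fr$ptr + 1L
        nb <- nbrs[[fr$ptr]]
        to <- nb[1]; eid <- nb[2]
        if (eid == fr$parentEdge) next
        if (disc[to] != 0L) {
          low[node] <- min(low[node], disc[to])
        } else {
          stack[[length(stack) + 1L]] <- list(node = to, parentEdge = eid,
                                              ptr = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          par <- stack[[length(stack)]]$node
          low[par] <- min(low[par], low[node])
          if (low[node] > disc[par]) out[fr$parentEdge] <- TRUE
        }
      }
    }
  }
  out
}

#' Structural summary of a multigraph
#'
#' Degree sequence (loops counting twice), cubicness, bridges (by standard
#' 2-edge-connectivity; loops and parallel edges are never bridges) and the
#' partition of the edges into 2-edge-connected blocks.
#'
#' @param G a [LabeledMultigraph-class].
#' @return A [GraphStats-class] object.
#' @export
graphStats <- function(G) {
  stopifnot(is(G, "LabeledMultigraph"))
  e <- G@edges
  isBridge <- .findBridges(e$u, e$v, G@vertices)
  blocks <- list()
  if (nrow(e)) {
    loops <- which(e$u == e$v)
    nonloop <- which(e$u != e$v)
    if (length(nonloop)) {
      ig <- igraph::graph_from_data_frame(
        data.frame(from = as.character(e$u[nonloop]),
                   to = as.character(e$v[nonloop])),
        directed = FALSE,
        vertices = data.frame(name = as.character(G@vertices)))
      bc <- igraph::biconnected_components(ig)
      for (ce in bc$component_edges)
        blocks[[length(blocks) + 1L]] <- e$label[nonloop[as.integer(ce)]]
    }
    for (i in loops)          # a loop is a block of its own
      blocks[[length(blocks) + 1L]] <- e$label[i]
  }
  new("GraphStats",
      nVertices = nVertices(G), nEdges = nEdges(G),
      degreeSequence = unname(.degrees(G)), isCubic = .isCubic(G),
      bridges = e$label[isBridge], blocks = blocks)
}

# component id per edge (indices into the supplied edge vectors)
.edgeComponents <- function(u, v) {
  m <- length(u)
  if (m == 0L) return(integer(0))
  verts <- sort(unique(c(u, v)))
  parent <- seq_along(verts)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(m)) {
    a <- find(match(u[i], verts)); b <- find(match(v[i], verts))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(match(u, verts), find, integer(1))
  match(roots, sort(unique(roots)))
}

setMethod("show", "GraphStats", function(object) {
  cat(sprintf("GraphStats: %d vertices, %d edges%s\n",
              object@nVertices, object@nEdges,
              if (object@isCubic) " (cubic)" else ""))
  cat("  degrees:", paste(object@degreeSequence, collapse = " "), "\n")
  cat("  bridges:", if (length(object@bridges))
    paste(object@bridges, collapse = ", ") else "none", "\n")
  cat(sprintf("  blocks: %d\n", length(object@blocks)))
})

# ------------------------------------------------------------ truncation --

#' Structural truncation of a cubic multigraph
#'
#' Inserts two vertices into every edge, then replaces the star of every
#' original degree-3 vertex by a triangle (the Y-delta transform).  The
#' result has 2m vertices and 3m edges for an m-edge cubic input, and is
#' again cubic.  The image of original edge `lab` is labeled `lab'`; the
#' three triangle edges at original vertex j are labeled `bj_1`, `bj_2`,
#' `bj_3`.
#'
#' @param G a cubic [LabeledMultigraph-class] (loops permitted).
#' @return The truncated [LabeledMultigraph-class].
#' @examples
#' prismLike <- structuralTruncate(builtinGraph("theta"))
#' @export
structuralTruncate <- function(G) {
  stopifnot(is(G, "LabeledMultigraph"))
  deg <- .degrees(G)
  if (any(deg != 3L))
    .stopPrecondition("graph is not cubic: vertex %s has degree %d",
                      names(deg)[deg != 3L][1], deg[deg != 3L][1])
  e <- G@edges
  m <- nrow(e)
  # subdivision vertex for (edge k, side s in 1:2) -> 0-based id
  subVertex <- function(k, s) 2L * (k - 1L) + s - 1L
  outU <- integer(0); outV <- integer(0); outLab <- character(0)
  for (k in seq_len(m)) {
    outU <- c(outU, subVertex(k, 1L))
    outV <- c(outV, subVertex(k, 2L))
    outLab <- c(outLab, paste0(e$label[k], "'"))
  }
  for (j in G@vertices) {
    halves <- list()
    for (k in seq_len(m)) {
      if (e$u[k] == j) halves[[length(halves) + 1L]] <- c(k, 1L)
      if (e$v[k] == j) halves[[length(halves) + 1L]] <- c(k, 2L)
    }
    stopifnot(length(halves) == 3L)
    ends <- vapply(halves, function(h) subVertex(h[1], h[2]), integer(1))
    pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    for (t in 1:3) {
      outU <- c(outU, ends[pairs[[t]][1]])
      outV <- c(outV, ends[pairs[[t]][2]])
      outLab <- c(outLab, paste0("b", j, "_", t))
    }
  }
  labeledMultigraph(0:(2L * m - 1L), data.frame(
    u = outU, v = outV, label = outLab, stringsAsFactors = FALSE))
}

# labels of the truncation, grouped for two-label collapse
.truncationLabelFamilies <- function(G) {
  list(a = paste0(G@edges$label, "'"),
       b = as.vector(t(outer(G@vertices, 1:3,
                             function(j, t) paste0("b", j, "_", t)))))
}

# ------------------------------------------------------------- planarity --

# Planarity certificate for Hamiltonian graphs: find a Hamiltonian cycle by
# backtracking, then the graph is planar iff the interlacement (conflict)
# graph of the remaining chords is bipartite.  Sound and complete on
# Hamiltonian inputs; errors when no Hamiltonian cycle exists.  Loops are
# ignored (they never obstruct planarity).
.isPlanarHamiltonian <- function(G) {
  e <- G@edges[G@edges$u != G@edges$v, , drop = FALSE]
  verts <- G@vertices
  nV <- length(verts)
  if (nV <= 2L) return(TRUE)
  adj <- lapply(seq_len(nV), function(i) integer(0))
  for (k in seq_len(nrow(e))) {
    a <- match(e$u[k], verts); b <- match(e$v[k], verts)
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  path <- integer(nV); inPath <- logical(nV)
  path[1] <- 1L; inPath[1] <- TRUE
  found <- FALSE
  rec <- function(depth) {
    if (found) return()
    if (depth == nV) {
      if (1L %in% adj[[path[nV]]]) found <<- TRUE
      return()
    }
    for (nb in adj[[path[depth]]]) {
      if (!inPath[nb]) {
        path[depth + 1L] <<- nb; inPath[nb] <<- TRUE
        rec(depth + 1L)
        if (found) return()
        inPath[nb] <<- FALSE
      }
    }
  }
  rec(1L)
  if (!found)
    .stopPrecondition("planarity certificate needs a Hamiltonian cycle")
  pos <- integer(nV); pos[path] <- seq_len(nV)
  # chords = edges not consecutive on the cycle (one cycle copy per slot)
  onCycle <- logical(nrow(e))
  usedSlot <- logical(nV)
  for (k in seq_len(nrow(e))) {
    a <- pos[match(e$u[k], verts)]; b <- pos[match(e$v[k], verts)]
    lo <- min(a, b); hi <- max(a, b)
    slot <- if (hi - lo == 1L) lo else if (lo == 1L && hi == nV) nV else NA
    if (!is.na(slot) && !usedSlot[slot]) {
      onCycle[k] <- TRUE; usedSlot[slot] <- TRUE
    }
  }
  chords <- which(!onCycle)
  cp <- lapply(chords, function(k) {
    sort(c(pos[match(e$u[k], verts)], pos[match(e$v[k], verts)]))
  })
  nC <- length(chords)
  if (nC <= 1L) return(TRUE)
  conflict <- function(x, y) {
    (x[1] < y[1] && y[1] < x[2] && x[2] < y[2]) ||
    (y[1] < x[1] && x[1] < y[2] && y[2] < x[2])
  }
  color <- integer(nC)
  for (s in seq_len(nC)) {
    if (color[s] != 0L) next
    color[s] <- 1L
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (t in seq_len(nC)) {
        if (t == cur || !conflict(cp[[cur]], cp[[t]])) next
        if (color[t] == 0L) {
          color[t] <- 3L - color[cur]
          queue <- c(queue, t)
        } else if (color[t] == color[cur]) return(FALSE)
      }
    }
  }
  TRUE
}

# igraph view of the multigraph (used for isomorphism checks in tests)
.asIgraph <- function(G) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(G@edges$u), to = as.character(G@edges$v)),
    directed = FALSE,
    vertices = data.frame(name = as.character(G@vertices)))
}
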