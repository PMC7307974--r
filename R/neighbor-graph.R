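#' Build a neighbourhood graph from an edge list
#'
#' Constructs the undirected adjacency structure used by the ICAR priors.
#' Edges may be supplied in either orientation and with duplicates; the
#' symmetric closure is taken and duplicates collapsed.
#'
#' @param n number of nodes (positive integer).
#' @param edges two-column matrix (or data.frame) of node pairs, 1-based.
#'   A zero-row matrix gives the empty graph.
#' @return A [NeighborGraph-class] object.
#' @examples
#' g <- neighborGraph(3, rbind(c(1, 2), c(2, 3)))
#' neighborCounts(g) # 1 2 1
#' @export
neighborGraph <- function(n, edges = matrix(integer(), 0L, 2L)) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("'n' must be a single positive integer")
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), 0L, 2L)
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n)) {
      stop("edge endpoints must be node indices in 1..n")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, sort)
  }
  comp <- .componentsFromAdj(n, adj)
  new("NeighborGraph",
    nNodes = n, edges = edges, neighborCounts = as.integer(deg),
    componentLabels = comp, adjacency = adj
  )
}

# breadth-first connected components; isolated nodes are singletons
.componentsFromAdj <- function(n, adj) {
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      lab[s] <- cur
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        nb <- adj[[v]]
        fresh <- nb[lab[nb] == 0L]
        lab[fresh] <- cur
        queue <- c(queue, fresh)
      }
    }
  }
  lab
}

#' Temporal path graph for random-walk (RW1) priors
#'
#' The temporal analogue of the spatial ICAR adjacency: time points h and t
#' are neighbours iff |h - t| = 1, so the ICAR prior on this graph is a
#' first-order Gaussian random walk.
#'
#' @param T number of ordered time points (>= 2).
#' @return A [NeighborGraph-class] path graph on `T` nodes.
#' @export
temporalPathGraph <- function(T) {
  T <- as.integer(T)
  if (length(T) != 1L || is.na(T) || T < 2L) {
    stop("'T' must be an integer >= 2")
  }
  neighborGraph(T, cbind(seq_len(T - 1L), 2:T))
}

#' Rook-neighbourhood lattice graph
#'
#' A rows-by-cols regular grid with horizontal and vertical adjacency, used
#' as a stand-in geography for simulation studies at configurable size.
#' Node (r, c) has index `(r - 1) * cols + c`.
#'
#' @param rows,cols grid dimensions, with `rows * cols >= 2`.
#' @return A [NeighborGraph-class] object with `r(c-1) + c(r-1)` edges.
#' @export
latticeGraph <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L || rows * cols < 2L) {
    stop("'rows * cols' must be at least 2")
  }
  idx <- function(r, c) (r - 1L) * cols + c
  e <- vector("list", 2L)
  horiz <- if (cols > 1L) {
    r <- rep(seq_len(rows), each = cols - 1L)
    c <- rep(seq_len(cols - 1L), times = rows)
    cbind(idx(r, c), idx(r, c + 1L))
  } else NULL
  vert <- if (rows > 1L) {
    r <- rep(seq_len(rows - 1L), each = cols)
    c <- rep(seq_len(cols), times = rows - 1L)
    cbind(idx(r, c), idx(r + 1L, c))
  } else NULL
  neighborGraph(rows * cols, rbind(horiz, vert))
}

#' Read a GAL-format neighbour list
#'
#' Reads the plain-text GAL spatial-weights format: a header line whose last
#' field is the node count, then for each node a line `id n_neighbors`
#' followed by a line of neighbour ids. Files indexed from 0 are detected
#' (a node id 0 appears) and converted to the 1-based indexing used
#' internally, with a message.
#'
#' @param path file path.
#' @return A [NeighborGraph-class] object.
#' @export
readGAL <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GAL file")
  header <- as.integer(strsplit(lines[[1L]], "\\s+")[[1L]])
  n <- header[[length(header)]]
  if (is.na(n) || n < 1L) stop("invalid GAL header")
  toks <- lapply(lines[-1L], function(l) as.integer(strsplit(l, "\\s+")[[1L]]))
  ids <- integer(); nbrs <- vector("list", 0L)
  k <- 1L
  while (k <= length(toks)) {
    hd <- toks[[k]]
    if (length(hd) != 2L) stop("malformed GAL node header at record ", length(ids) + 1L)
    ids <- c(ids, hd[[1L]])
    nn <- hd[[2L]]
    if (nn > 0L) {
      k <- k + 1L
      if (k > length(toks) || length(toks[[k]]) != nn) {
        stop("malformed GAL neighbour list for node ", hd[[1L]])
      }
      nbrs <- c(nbrs, list(toks[[k]]))
    } else {
      nbrs <- c(nbrs, list(integer()))
    }
    k <- k + 1L
  }
  if (length(ids) != n) stop("GAL file declares ", n, " nodes but lists ", length(ids))
  allIds <- c(ids, unlist(nbrs))
  if (any(allIds == 0L)) {
    message("GAL file uses 0-based node ids; converting to 1-based")
    ids <- ids + 1L
    nbrs <- lapply(nbrs, function(x) x + 1L)
  }
  edges <- do.call(rbind, lapply(seq_along(ids), function(j) {
    if (length(nbrs[[j]])) cbind(ids[[j]], nbrs[[j]]) else NULL
  }))
  if (is.null(edges)) edges <- matrix(integer(), 0L, 2L)
  neighborGraph(n, edges)
}

#' @rdname nNodes
#' @export
setMethod("nNodes", "NeighborGraph", function(x) x@nNodes)

#' @rdname edgeMatrix
#' @export
setMethod("edgeMatrix", "NeighborGraph", function(x) x@edges)

#' @rdname neighborCounts
#' @export
setMethod("neighborCounts", "NeighborGraph", function(x) x@neighborCounts)

#' @rdname componentLabels
#' @export
setMethod("componentLabels", "NeighborGraph", function(x) x@componentLabels)

#' @rdname adjacencyList
#' @export
setMethod("adjacencyList", "NeighborGraph", function(x) x@adjacency)

setMethod("show", "NeighborGraph", function(object) {
  cat("NeighborGraph with", object@nNodes, "nodes,",
      nrow(object@edges), "edges,",
      max(object@componentLabels), "connected component(s)\n")
})

#' ICAR pairwise-difference quadratic form
#'
#' Computes the kernel of the joint intrinsic CAR density,
#' `sum over edges (i,j) of (x_i - x_j)^2`, equal to `x' (D - W) x` with D
#' the diagonal of neighbour counts. Zero iff x is constant within every
#' connected component.
#'
#' @param x numeric vector of length `nNodes(graph)`.
#' @param graph a [NeighborGraph-class].
#' @return Non-negative scalar.
#' @export
icarQuadform <- function(x, graph) {
  stopifnot(is(graph, "NeighborGraph"))
  if (length(x) != graph@nNodes) stop("'x' must have one entry per node")
  e <- graph@edges
  if (!nrow(e)) return(0)
  sum((x[e[, 1L]] - x[e[, 2L]])^2)
}

#' Joint ICAR log-density (improper, up to a constant)
#'
#' The joint counterpart of the conditional ICAR specification in which each
#' node is Normal around the mean of its neighbours with variance
#' `sigma2 / N_i`:
#' `-icarQuadform(x, graph) / (2 * sigma2) - ((n - c) / 2) * log(sigma2)`,
#' where c is the number of connected components (the rank deficiency of the
#' precision). The log-variance term is retained so the variance
#' hyperparameter is identifiable; additive constants are dropped. The
#' density is improper: it is invariant to adding a constant per component,
#' so `x` should be kept identified via [sumToZero()].
#'
#' @param x numeric vector of length `nNodes(graph)`.
#' @param graph a [NeighborGraph-class].
#' @param sigma2 positive conditional variance parameter.
#' @return Scalar log-density (up to an additive constant).
#' @export
icarLogpdf <- function(x, graph, sigma2) {
  stopifnot(is(graph, "NeighborGraph"))
  if (length(sigma2) != 1L || is.na(sigma2) || sigma2 <= 0) {
    stop("'sigma2' must be a positive scalar")
  }
  nComp <- max(graph@componentLabels)
  -icarQuadform(x, graph) / (2 * sigma2) -
    ((graph@nNodes - nComp) / 2) * log(sigma2)
}

#' Centre a vector within each connected component
#'
#' Subtracts the component-wise mean, imposing the sum-to-zero constraints
#' that identify the improper ICAR priors. Idempotent; isolated nodes are
#' centred alone (set to zero).
#'
#' @param x numeric vector of length `nNodes(graph)`.
#' @param graph a [NeighborGraph-class].
#' @return Numeric vector whose sum within every component is zero.
#' @export
sumToZero <- function(x, graph) {
  stopifnot(is(graph, "NeighborGraph"))
  if (length(x) != graph@nNodes) stop("'x' must have one entry per node")
  lab <- graph@componentLabels
  x - ave(x, lab)
}
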