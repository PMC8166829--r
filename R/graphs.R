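#' Weighted interaction network
#'
#' Container for the static weighted undirected graphs the dynamics run on.
#' A graph on `n` vertices is stored as a dense symmetric weight matrix `w`
#' with zero diagonal; `d[i] = sum_j w[i, j]` is vertex `i`'s interaction
#' strength (weighted degree). Every graph must satisfy the model's standing
#' assumptions: non-negative symmetric weights, no self-loops, and no
#' isolated vertices (`d[i] > 0` for all `i`).
#'
#' @param w square numeric matrix of edge weights.
#' @param labels optional vector of original vertex labels (kept as an
#'   attribute; internally vertices are `1..n`).
#' @return An object of class `weighted_graph`: a list with elements `n`,
#'   `w`, and `d`.
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
#' strengths(g)
#' @export
weighted_graph <- function(w, labels = NULL) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  n <- nrow(w)
  if (n < 2L) stop("population size must be at least 2")
  storage.mode(w) <- "double"
  if (any(!is.finite(w))) stop("weights must be finite")
  if (any(w < 0)) stop("negative edge weight")
  if (max(abs(w - t(w))) > 0) stop("weight matrix must be symmetric")
  if (any(diag(w) != 0)) stop("self-loop: diagonal of weight matrix must be zero")
  d <- rowSums(w)
  if (any(d <= 0)) stop("isolated vertex: every vertex needs d_i > 0")
  dimnames(w) <- NULL
  structure(list(n = n, w = w, d = d, labels = labels),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  ne <- sum(x$w[upper.tri(x$w)] > 0)
  cat(sprintf("weighted_graph: %d vertices, %d edges, total strength %.6g\n",
              x$n, ne, sum(x$d)))
  invisible(x)
}

#' Vertex strengths
#'
#' @param g a `weighted_graph`.
#' @return Numeric vector `d` of weighted degrees.
#' @export
strengths <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  g$d
}

#' Build a graph from an edge list
#'
#' Vertex labels may be any sortable values (typically integers `0..n-1`);
#' they are mapped to internal indices `1..n` in sorted order. Each
#' undirected edge must appear exactly once; a repeated vertex pair is
#' rejected as contradictory.
#'
#' @param edges a three-column matrix or data frame `(u, v, weight)`, or a
#'   two-column one (all weights 1).
#' @return A [weighted_graph()].
#' @examples
#' make_graph(rbind(c(0, 1, 1), c(1, 2, 2)))$d # path: 1, 3, 2
#' @export
make_graph <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) == 2L) edges$w <- 1
  if (ncol(edges) != 3L) stop("edges must have columns (u, v, weight)")
  names(edges) <- c("u", "v", "w")
  edges$w <- as.numeric(edges$w)
  if (any(!is.finite(edges$w)) || any(edges$w < 0)) {
    stop("edge weights must be finite and non-negative")
  }
  if (any(edges$u == edges$v)) stop("self-loop edge not allowed")
  labs <- sort(unique(c(edges$u, edges$v)))
  n <- length(labs)
  i <- match(edges$u, labs)
  j <- match(edges$v, labs)
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) stop("duplicate edge between the same vertex pair")
  w <- matrix(0, n, n)
  w[cbind(i, j)] <- edges$w
  w[cbind(j, i)] <- edges$w
  weighted_graph(w, labels = labs)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

from_igraph <- function(ig) {
  w <- igraph::as_adjacency_matrix(ig, sparse = FALSE)
  weighted_graph(w)
}

connected_retry <- function(draw, max_tries = 1000L) {
  for (t in seq_len(max_tries)) {
    ig <- draw()
    if (igraph::is_connected(ig)) return(ig)
  }
  stop("failed to draw a connected graph after ", max_tries, " attempts")
}

#' Random graph generators
#'
#' `random_graph()` draws an Erdős–Rényi G(N, p) graph with
#' `p = kbar / (N - 1)` (so mean degree is about `kbar`), resampled until
#' connected. `random_regular()` draws a connected random k-regular graph.
#' `scale_free()` grows a Barabási–Albert preferential-attachment network
#' with `m = round(kbar / 2)` edges per new vertex (connected by
#' construction). All emit unit edge weights; reweight with
#' [assign_weights()].
#'
#' @param n number of vertices.
#' @param kbar target mean degree (must be below `n - 1`).
#' @param k exact degree for the regular graph (`n * k` must be even).
#' @param seed integer seed; the generators are reproducible given the seed.
#' @return A [weighted_graph()] with all edge weights equal to 1.
#' @examples
#' g <- random_regular(6, 2, seed = 1)
#' strengths(g) # all 2
#' @export
random_graph <- function(n, kbar, seed = NULL) {
  if (kbar >= n - 1) stop("kbar must be below n - 1")
  if (kbar <= 0) stop("kbar must be positive")
  if (!is.null(seed)) set.seed(seed)
  ig <- connected_retry(function() igraph::sample_gnp(n, kbar / (n - 1)))
  from_igraph(ig)
}

#' @rdname random_graph
#' @export
random_regular <- function(n, k, seed = NULL) {
  if (k < 1 || k > n - 1) stop("infeasible degree k")
  if ((n * k) %% 2 != 0) stop("n * k must be even for a k-regular graph")
  if (!is.null(seed)) set.seed(seed)
  ig <- connected_retry(function() igraph::sample_k_regular(n, k))
  from_igraph(ig)
}

#' @rdname random_graph
#' @export
scale_free <- function(n, kbar, seed = NULL) {
  m <- max(1L, round(kbar / 2))
  if (m >= n) stop("kbar too large for n")
  if (!is.null(seed)) set.seed(seed)
  ig <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  ig <- igraph::simplify(ig)
  from_igraph(ig)
}

#' Assign edge weights to an unweighted graph
#'
#' Reweights every existing edge of a unit-weight graph with one independent
#' draw per undirected edge: `homogeneous` keeps all weights at 1;
#' `uniform_int` draws uniformly from the integers 1..10; `zipf` draws from
#' a discrete power law with exponent 3 (pmf proportional to `k^-3`,
#' truncated at 100). Topology is never altered.
#'
#' @param g a [weighted_graph()] with all existing edge weights equal to 1.
#' @param scheme one of `"homogeneous"`, `"uniform_int"`, `"zipf"`.
#' @param seed integer seed.
#' @return A [weighted_graph()] with the same edges and new weights.
#' @export
assign_weights <- function(g, scheme = c("homogeneous", "uniform_int", "zipf"),
                           seed = NULL) {
  stopifnot(inherits(g, "weighted_graph"))
  scheme <- match.arg(scheme)
  up <- upper.tri(g$w)
  if (!all(g$w[up] %in% c(0, 1))) {
    stop("assign_weights expects a unit-weight (unweighted) graph")
  }
  if (scheme == "homogeneous") return(g)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(up & g$w > 0)
  ne <- length(idx)
  wts <- switch(scheme,
    uniform_int = sample.int(10L, ne, replace = TRUE),
    zipf = sample.int(100L, ne, replace = TRUE,
                      prob = (1:100)^(-3) / sum((1:100)^(-3))))
  w <- g$w
  w[idx] <- wts
  w[lower.tri(w)] <- t(w)[lower.tri(w)] # mirror the upper triangle
  weighted_graph(w, labels = g$labels)
}

#' Enumerate connected graphs up to isomorphism
#'
#' Iterates all `2^(n(n-1)/2)` labeled simple graphs on `n` vertices, keeps
#' the connected ones, and deduplicates by canonical form (BLISS, via
#' igraph), returning one unit-weight representative per isomorphism class
#' in a deterministic order. There are 1, 2, 6, 21, 112 classes for
#' n = 2..6.
#'
#' @param n number of vertices (2..7; exhaustive iteration guards the
#'   combinatorial blow-up).
#' @return List of [weighted_graph()] objects.
#' @export
enumerate_connected_graphs <- function(n) {
  if (n < 2 || n > 7) stop("n must be between 2 and 7")
  n <- as.integer(n)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ne <- nrow(pr)
  bit <- bitwShiftL(1L, 0:(ne - 1L))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  keys <- character(0)
  for (mask in seq_len(2^ne - 1)) {
    sel <- bitwAnd(mask, bit) != 0L
    if (sum(sel) < n - 1L) next # too few edges to connect n vertices
    w <- matrix(0, n, n)
    w[pr[sel, , drop = FALSE]] <- 1
    w <- w + t(w)
    # connectivity via boolean reachability from vertex 1
    reach <- logical(n); reach[1] <- TRUE
    repeat {
      nxt <- reach | (w %*% reach > 0)
      if (all(nxt == reach)) break
      reach <- as.vector(nxt)
    }
    if (!all(reach)) next
    if (any(rowSums(w) == 0)) next
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
    cp <- igraph::canonical_permutation(ig)$labeling
    cig <- igraph::permute(ig, cp)
    el <- igraph::as_edgelist(cig)
    key <- paste(el[order(el[, 1], el[, 2]), ], collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <- weighted_graph(
      igraph::as_adjacency_matrix(cig, sparse = FALSE))
    keys <- c(keys, key)
  }
  out[order(vapply(out, function(g) sum(g$d) / 2, 0), keys)]
}

#' Read and write edge-list files
#'
#' Plain-text edge lists, one undirected edge per line as whitespace-
#' separated `u v w` (an optional header line is skipped; `#` comments
#' ignored). On write, vertices are labeled `0..n-1` and weights are printed
#' with full precision, so a write/read round trip reproduces the graph
#' exactly.
#'
#' @param path file path.
#' @param g a [weighted_graph()].
#' @return `read_edgelist()` returns a [weighted_graph()];
#'   `write_edgelist()` returns `path` invisibly.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty edge list")
  toks <- strsplit(lines, "\\s+")
  if (is.na(suppressWarnings(as.numeric(toks[[1]][1])))) { # header line
    toks <- toks[-1]
    if (!length(toks)) stop("edge list has a header but no edges")
  }
  nc <- lengths(toks)
  if (any(nc != nc[1]) || !nc[1] %in% 2:3) {
    stop("malformed edge-list line: expected 'u v [w]'")
  }
  m <- do.call(rbind, toks)
  u <- m[, 1]; v <- m[, 2]
  w <- if (nc[1] == 3L) suppressWarnings(as.numeric(m[, 3])) else rep(1, nrow(m))
  if (any(is.na(w))) stop("malformed edge weight")
  un <- suppressWarnings(as.numeric(u)); vn <- suppressWarnings(as.numeric(v))
  if (!any(is.na(un)) && !any(is.na(vn))) { u <- un; v <- vn }
  make_graph(data.frame(u = u, v = v, w = w))
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "weighted_graph"))
  idx <- which(upper.tri(g$w) & g$w > 0, arr.ind = TRUE)
  lines <- sprintf("%d %d %s", idx[, 1] - 1L, idx[, 2] - 1L,
                   formatC(g$w[idx], format = "g", digits = 17))
  writeLines(lines, path)
  invisible(path)
}

#' Write an enumerated graph set to a directory
#'
#' Serializes a list of graphs as numbered edge-list files plus an
#' `index.tsv` with vertex and edge counts.
#'
#' @param graphs list of [weighted_graph()] objects.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_graph_set <- function(graphs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("graph_%03d.edges", seq_along(graphs))
  for (i in seq_along(graphs)) {
    write_edgelist(graphs[[i]], file.path(dir, files[i]))
  }
  idx <- data.frame(
    file = files,
    n = vapply(graphs, function(g) g$n, 0L),
    edges = vapply(graphs, function(g) sum(g$w[upper.tri(g$w)] > 0), 0))
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
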