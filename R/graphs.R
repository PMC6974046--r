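#' Interaction graphs
#'
#' An `interaction_graph` is a fixed, undirected, simple graph on `n`
#' individuals (vertices `1..n`), determined before the dynamics start and
#' immutable thereafter. Neighbors on the graph are the interaction partners
#' whose pairwise prisoner's dilemma payoffs sum to an individual's total
#' payoff, and connectedness on the graph defines which sets of individuals
#' may form an updating coalition.
#'
#' @param n positive integer, number of individuals (vertices).
#' @param edges two-column integer matrix of vertex pairs (1-based), one row
#'   per undirected edge; may have zero rows. Self-loops and duplicate edges
#'   are rejected.
#' @return An object of class `interaction_graph` with fields `n`, `edges`
#'   (canonicalized: each row sorted, rows in lexicographic order), and a
#'   precomputed adjacency list `adj`.
#' @examples
#' g <- interaction_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
#' edge_density(g)
#' @export
interaction_graph <- function(n, edges = matrix(integer(0), ncol = 2)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("`n` must be a single positive integer")
  n <- as.integer(n)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(0), ncol = 2)
  if (ncol(edges) != 2L) stop("`edges` must be a two-column matrix")
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0L) {
    if (anyNA(edges) || any(edges < 1L) || any(edges > n))
      stop("edge endpoints must be vertex ids in 1..n")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, c(2L, 1L)]
    key <- (edges[, 1L] - 1) * as.double(n) + (edges[, 2L] - 1)
    if (anyDuplicated(key))
      stop("duplicate edges are not allowed")
    edges <- edges[order(key), , drop = FALSE]
  }
  adj <- rep(list(integer(0)), n)
  if (nrow(edges) > 0L) {
    fr <- c(edges[, 1L], edges[, 2L])
    to <- c(edges[, 2L], edges[, 1L])
    ord <- order(fr, to)
    adj <- unname(split(to[ord], factor(fr[ord], levels = seq_len(n))))
  }
  structure(
    list(n = n, edges = edges, adj = adj, cache = new.env(parent = emptyenv())),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d vertices, %d edges (density %.4f)\n",
              x$n, nrow(x$edges), edge_density(x)))
  invisible(x)
}

n_vertices <- function(g) g$n
n_edges <- function(g) nrow(g$edges)

check_graph <- function(g) {
  if (!inherits(g, "interaction_graph"))
    stop("expected an `interaction_graph` object")
  g
}

check_vertices <- function(g, S) {
  S <- as.integer(S)
  if (length(S) == 0L) stop("vertex set must be nonempty")
  if (anyNA(S) || any(S < 1L) || any(S > g$n))
    stop("unknown vertex id (ids are 1..n)")
  if (anyDuplicated(S)) stop("vertex set contains duplicates")
  S
}

#' Generate an Erdos-Renyi random graph at an exact edge density
#'
#' Draws a G(n, m) graph: exactly `m = round(e * n * (n - 1) / 2)` edges
#' chosen uniformly at random among all m-edge graphs on `n` vertices.  The
#' fixed-edge-count variant is used (rather than independent edge coin
#' flips) so that the realized edge density equals the requested `e` up to
#' rounding of the edge count: density is defined as the ratio of edges
#' present to edges possible.  The graph may be disconnected; no
#' connectivity conditioning is applied.
#'
#' @param n number of vertices (at least 2).
#' @param e target edge density in `[0, 1]`.
#' @param seed optional integer; if supplied, `set.seed(seed)` is called
#'   first so the same seed always yields the same graph.
#' @return an [interaction_graph].
#' @examples
#' g <- generate_erdos_renyi(32, 0.10, seed = 1)
#' n_edges <- nrow(g$edges)  # exactly round(0.10 * 496) = 50
#' @export
generate_erdos_renyi <- function(n, e, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != floor(n))
    stop("`n` must be a single integer >= 2")
  if (!is.numeric(e) || length(e) != 1L || is.na(e) || e < 0 || e > 1)
    stop("edge density `e` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  npairs <- n * (n - 1) / 2
  m <- round(e * npairs)
  idx <- if (m > 0) sort(sample.int(npairs, m)) else integer(0)
  interaction_graph(n, pair_index_decode(idx, n))
}

# Decode 1-based lexicographic pair indices into (i, j) with i < j:
# index 1 -> (1,2), 2 -> (1,3), ..., n-1 -> (1,n), n -> (2,3), ...
pair_index_decode <- function(idx, n) {
  if (length(idx) == 0L) return(matrix(integer(0), ncol = 2))
  idx <- as.double(idx)
  # vertex i is the smallest i with cum(i) >= idx, cum(i) = sum_{t<=i}(n-t)
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * idx))
  cum_prev <- (i - 1) * n - i * (i - 1) / 2
  j <- idx - cum_prev + i
  cbind(as.integer(i), as.integer(j))
}

#' Generate a Watts-Strogatz small-world graph
#'
#' Starts from a ring lattice on `n` vertices in which every vertex is
#' joined to its `ws_mean_degree / 2` nearest neighbors on each side, then
#' rewires each edge independently with probability `ws_rewire_prob`,
#' keeping one endpoint and moving the other to a uniformly chosen vertex
#' that creates neither a self-loop nor a duplicate edge.  The edge count
#' `n * ws_mean_degree / 2` is conserved exactly, so the realized edge
#' density is `ws_mean_degree / (n - 1)` regardless of the rewiring
#' probability.
#'
#' @param n number of vertices.
#' @param ws_mean_degree even integer in `[2, n)`, the lattice degree.
#' @param ws_rewire_prob rewiring probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return an [interaction_graph].
#' @export
generate_watts_strogatz <- function(n, ws_mean_degree, ws_rewire_prob, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 3 || n != floor(n))
    stop("`n` must be a single integer >= 3")
  k <- ws_mean_degree
  if (!is.numeric(k) || length(k) != 1L || k != floor(k) || k %% 2 != 0)
    stop("`ws_mean_degree` must be an even integer")
  if (k < 2 || k >= n)
    stop("`ws_mean_degree` must satisfy 2 <= ws_mean_degree < n")
  if (!is.numeric(ws_rewire_prob) || ws_rewire_prob < 0 || ws_rewire_prob > 1)
    stop("`ws_rewire_prob` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  half <- as.integer(k / 2)
  # ring lattice edges, one row per (v, v+d mod n), d = 1..half
  fr <- rep(seq_len(n), half)
  d <- rep(seq_len(half), each = n)
  to <- ((fr - 1L + d) %% n) + 1L
  edges <- cbind(pmin(fr, to), pmax(fr, to))
  edges <- unique(edges)  # when k/2 == n/2 the longest chords coincide
  has_edge <- matrix(FALSE, n, n)
  has_edge[edges] <- TRUE
  has_edge[edges[, c(2L, 1L)]] <- TRUE
  rewire <- stats::runif(nrow(edges)) < ws_rewire_prob
  for (r in which(rewire)) {
    u <- edges[r, 1L]; v <- edges[r, 2L]
    candidates <- which(!has_edge[u, ] & seq_len(n) != u)
    if (length(candidates) == 0L) next
    w <- candidates[sample.int(length(candidates), 1L)]
    has_edge[u, v] <- has_edge[v, u] <- FALSE
    has_edge[u, w] <- has_edge[w, u] <- TRUE
    edges[r, ] <- c(min(u, w), max(u, w))
  }
  interaction_graph(n, edges)
}

#' Edge density of a graph
#'
#' The ratio of the number of edges present to the number of possible
#' edges, `n(n-1)/2`.
#'
#' @param g an [interaction_graph] with at least 2 vertices.
#' @return a number in `[0, 1]`.
#' @export
edge_density <- function(g) {
  check_graph(g)
  if (g$n < 2) stop("edge density requires at least 2 vertices")
  nrow(g$edges) / (g$n * (g$n - 1) / 2)
}

#' Is a vertex set connected in the induced subgraph?
#'
#' A set of individuals is a feasible (main-treatment) coalition exactly
#' when the subgraph induced by the set is connected, i.e. its members
#' interact with one another directly or indirectly without leaving the
#' set. Singletons are connected by convention.
#'
#' @param g an [interaction_graph].
#' @param S nonempty vector of vertex ids.
#' @return `TRUE` or `FALSE`.
#' @export
is_connected_induced <- function(g, S) {
  check_graph(g)
  S <- check_vertices(g, S)
  if (length(S) == 1L) return(TRUE)
  in_set <- logical(g$n)
  in_set[S] <- TRUE
  seen <- logical(g$n)
  stack <- S[1L]
  seen[S[1L]] <- TRUE
  found <- 1L
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- g$adj[[v]]
    nb <- nb[in_set[nb] & !seen[nb]]
    if (length(nb) > 0L) {
      seen[nb] <- TRUE
      found <- found + length(nb)
      stack <- c(stack, nb)
    }
  }
  found == length(S)
}

#' Is a vertex set a clique?
#'
#' The robustness treatment restricts coalitions to cliques: sets in which
#' every member is a neighbor of every other member. Singletons count as
#' cliques.
#'
#' @inheritParams is_connected_induced
#' @return `TRUE` or `FALSE`.
#' @export
is_clique <- function(g, S) {
  check_graph(g)
  S <- check_vertices(g, S)
  k <- length(S)
  if (k == 1L) return(TRUE)
  need <- k - 1L
  for (v in S) {
    if (sum(g$adj[[v]] %in% S) != need) return(FALSE)
  }
  TRUE
}

#' Enumerate all feasible coalitions of a given size
#'
#' Exhaustively lists the size-`k` vertex sets that satisfy the coalition
#' feasibility predicate: connected induced subgraphs (main treatment) or
#' cliques (robustness treatment). Enumeration is exact — no sampling — and
#' the result is cached on the graph per `(k, mode)`, since the graph is
#' immutable. Intended for the coalition sizes of the model (`k` up to 5)
#' on populations of a few dozen; a guard rejects problem sizes where
#' exhaustive enumeration would be unreasonable.
#'
#' @param g an [interaction_graph].
#' @param k coalition size, `1 <= k <= n`.
#' @param mode `"connected"` or `"clique"`.
#' @return an integer matrix with `k` rows; each column is one coalition,
#'   members sorted increasingly. Zero columns when no feasible coalition
#'   of size `k` exists.
#' @export
enumerate_feasible_coalitions <- function(g, k, mode = c("connected", "clique")) {
  check_graph(g)
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1L || k != floor(k) || k < 1 || k > g$n)
    stop("coalition size `k` must be an integer in 1..n")
  k <- as.integer(k)
  if (g$n > 512)
    stop("exhaustive coalition enumeration is limited to graphs with n <= 512")
  key <- paste0(mode, ":", k)
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  sets <- if (mode == "connected") {
    enum_connected_cpp(g$adj, g$n, k)
  } else {
    enum_cliques_cpp(g$adj, g$n, k)
  }
  g$cache[[key]] <- sets
  sets
}

#' Read / write plain-text edge lists
#'
#' The file format is one edge per line as two whitespace-separated
#' non-negative integers, with 0-based vertex ids; lines starting with `#`
#' are comments. `# n <count>` in a comment records the vertex count so
#' that trailing isolated vertices survive a round trip. In-memory graphs
#' use 1-based ids; conversion happens at this boundary.
#'
#' @param path file path.
#' @param n optional vertex count override when reading (otherwise taken
#'   from the `# n` header or the largest endpoint).
#' @return `read_edge_list()` returns an [interaction_graph];
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path, n = NULL) {
  lines <- readLines(path)
  header_n <- NULL
  edges <- matrix(integer(0), ncol = 2)
  rows <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (txt == "") next
    if (startsWith(txt, "#")) {
      hm <- regmatches(txt, regexec("^#\\s*n\\s+(\\d+)\\s*$", txt))[[1L]]
      if (length(hm) == 2L) header_n <- as.integer(hm[2L])
      next
    }
    tok <- strsplit(txt, "\\s+")[[1L]]
    if (length(tok) != 2L || !all(grepl("^[0-9]+$", tok)))
      stop(sprintf("line %d: expected two non-negative integers, got '%s'", ln, txt))
    u <- as.integer(tok[1L]); v <- as.integer(tok[2L])
    if (u == v)
      stop(sprintf("line %d: self-loop '%d %d' is not allowed", ln, u, v))
    rows[[ln]] <- c(u, v)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) > 0L) edges <- do.call(rbind, rows) + 1L
  nv <- if (!is.null(n)) as.integer(n)
        else if (!is.null(header_n)) header_n
        else if (nrow(edges) > 0L) max(edges) else 0L
  if (nv < 1L) stop("cannot determine vertex count of an empty edge list; pass `n`")
  key <- pmin(edges[, 1L], edges[, 2L]) * as.double(nv + 1L) +
         pmax(edges[, 1L], edges[, 2L])
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1L]
    stop(sprintf("duplicate edge '%d %d' in file", edges[dup, 1L] - 1L, edges[dup, 2L] - 1L))
  }
  interaction_graph(nv, edges)
}

#' @rdname read_edge_list
#' @param g an [interaction_graph] to write.
#' @export
write_edge_list <- function(g, path) {
  check_graph(g)
  lines <- c(sprintf("# n %d", g$n),
             sprintf("%d %d", g$edges[, 1L] - 1L, g$edges[, 2L] - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' Convert to an igraph object
#'
#' Convenience bridge for visualization and export (e.g. GraphML via
#' [igraph::write_graph()]); not used by the dynamics themselves.
#'
#' @param g an [interaction_graph].
#' @return an [igraph::graph] with the same vertices and edges.
#' @export
as_igraph <- function(g) {
  check_graph(g)
  ig <- igraph::make_empty_graph(g$n, directed = FALSE)
  igraph::add_edges(ig, as.vector(t(g$edges)))
}

#' @rdname as_igraph
#' @param path output file path.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}
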