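# Independent oracles used against the package's implementations. These
# deliberately avoid the package's own data structures and loops: payoffs
# are summed directly from an edge matrix, and connectivity is delegated
# to igraph.

# All labeled graphs on n vertices as edge matrices (bitmask over pairs).
all_graphs_edges <- function(n) {
  pairs <- t(utils::combn(n, 2))
  lapply(0:(2^nrow(pairs) - 1), function(mask) {
    pairs[bitwAnd(mask, bitwShiftL(1L, seq_len(nrow(pairs)) - 1L)) > 0L, ,
          drop = FALSE]
  })
}

# Total payoff of vertex i by direct summation over the edge matrix.
oracle_payoff <- function(edges, M, profile, i) {
  lab <- c("D", "C")
  tot <- 0
  if (nrow(edges) == 0L) return(0)
  for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1]; v <- edges[r, 2]
    if (u == i) tot <- tot + M[lab[profile[i] + 1], lab[profile[v] + 1]]
    if (v == i) tot <- tot + M[lab[profile[i] + 1], lab[profile[u] + 1]]
  }
  tot
}

# Payoff change of member i if every member of S switches to `target`.
oracle_switch_delta <- function(edges, M, profile, S, i, target) {
  new_prof <- profile
  new_prof[S] <- target
  oracle_payoff(edges, M, new_prof, i) - oracle_payoff(edges, M, profile, i)
}

# Connectivity of the induced subgraph via igraph.
oracle_connected <- function(n, edges, S) {
  if (length(S) == 1L) return(TRUE)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L) ig <- igraph::add_edges(ig, as.vector(t(edges)))
  sub <- igraph::induced_subgraph(ig, S)
  igraph::is_connected(sub)
}

# Clique test straight from the edge set.
oracle_clique <- function(edges, S) {
  if (length(S) == 1L) return(TRUE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  present <- key(edges[, 1], edges[, 2])
  pairs <- t(utils::combn(sort(S), 2))
  all(key(pairs[, 1], pairs[, 2]) %in% present)
}

# Canonical string form of a collection of vertex sets, order-free.
canon_sets <- function(m) {
  if (is.matrix(m)) {
    if (ncol(m) == 0L) return(character(0))
    sort(apply(m, 2, function(s) paste(sort(s), collapse = "-")))
  } else {
    sort(vapply(m, function(s) paste(sort(s), collapse = "-"), character(1)))
  }
}

random_small_graph <- function(n, p_edge = 0.4) {
  pairs <- t(utils::combn(n, 2))
  pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
}

benchmark_matrix <- function() pd_matrix_from_benefit_cost(3, 4)
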