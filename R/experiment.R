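#' Graph specification
#'
#' Declarative description of how the interaction graph of a run is
#' obtained: an Erdos-Renyi graph at exact edge density `e`, a
#' Watts-Strogatz small world, or a user-supplied edge-list file. For
#' Watts-Strogatz, a target density `e` may be given instead of a mean
#' degree; it is converted to the nearest even lattice degree
#' `e * (n - 1)` and the realized density `ws_mean_degree / (n - 1)` is
#' stored alongside the target.
#'
#' @param model `"erdos_renyi"`, `"watts_strogatz"` or `"user_edge_list"`.
#' @param n number of individuals.
#' @param e target edge density (Erdos-Renyi; optional for
#'   Watts-Strogatz).
#' @param ws_mean_degree even lattice degree (Watts-Strogatz).
#' @param ws_rewire_prob rewiring probability (Watts-Strogatz).
#' @param path edge-list file (user_edge_list).
#' @return an object of class `graph_spec`.
#' @export
graph_spec <- function(model = c("erdos_renyi", "watts_strogatz", "user_edge_list"),
                       n = 32, e = NULL, ws_mean_degree = NULL,
                       ws_rewire_prob = 0.1, path = NULL) {
  model <- match.arg(model)
  if (model == "erdos_renyi") {
    if (is.null(e)) stop("erdos_renyi needs a target edge density `e`")
    if (e < 0 || e > 1) stop("edge density `e` must lie in [0, 1]")
  }
  realized_e <- NULL
  if (model == "watts_strogatz") {
    if (is.null(ws_mean_degree)) {
      if (is.null(e)) stop("watts_strogatz needs `ws_mean_degree` or a target `e`")
      ws_mean_degree <- 2L * max(1L, round(e * (n - 1) / 2))
    }
    if (ws_mean_degree %% 2 != 0) stop("`ws_mean_degree` must be even")
    realized_e <- ws_mean_degree / (n - 1)
  }
  if (model == "user_edge_list" && is.null(path))
    stop("user_edge_list needs a file `path`")
  structure(list(model = model, n = as.integer(n), e = e,
                 ws_mean_degree = ws_mean_degree,
                 ws_rewire_prob = ws_rewire_prob,
                 realized_e = realized_e, path = path),
            class = "graph_spec")
}

build_graph <- function(spec) {
  if (inherits(spec, "interaction_graph")) return(spec)
  if (!inherits(spec, "graph_spec")) stop("expected a `graph_spec`")
  switch(spec$model,
    erdos_renyi = generate_erdos_renyi(spec$n, spec$e),
    watts_strogatz = generate_watts_strogatz(spec$n, spec$ws_mean_degree,
                                             spec$ws_rewire_prob),
    user_edge_list = read_edge_list(spec$path)
  )
}

#' Simulation configuration
#'
#' Full description of one model run: the graph (a [graph_spec] or an
#' already-built [interaction_graph]), the payoff matrix, the coalition
#' rule, the run length `T`, the initial condition, the measurement
#' window, the seed, and an optional collaboration schedule overriding
#' `p` on given period intervals (e.g. a collaboration-off phase).
#'
#' @param graph a [graph_spec] or [interaction_graph].
#' @param matrix a `payoff_matrix`.
#' @param rule a [coalition_rule].
#' @param T_periods number of update periods (at least 1; a zero-length
#'   run is rejected rather than returning the initial state).
#' @param init `"half_random"` (exactly n/2 cooperators at random
#'   positions; requires even n), `"all_cooperate"` or `"all_defect"`.
#' @param measure_window inclusive period interval `c(w_start, w_end)`
#'   over which cooperation is averaged; must lie within `[1, T]`.
#' @param seed integer seed governing the graph draw, the initial profile
#'   and the whole trajectory; `NULL` continues the current RNG stream.
#' @param schedule optional data.frame (or list of `c(from, to, p)`) of
#'   collaboration overrides; intervals must partition `[1, T]` exactly.
#' @param engine `"cpp"` (default) or `"reference"` (pure R; identical
#'   trajectories per seed).
#' @param record_profiles keep the full T-by-n strategy history (needed
#'   for [per_node_cooperation()] on non-default windows).
#' @param validate assert the weak-improvement guarantee after every
#'   update (testing aid).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(graph, matrix, rule, T_periods = 3000,
                              init = c("half_random", "all_cooperate", "all_defect"),
                              measure_window = c(2501, 3000), seed = NULL,
                              schedule = NULL, engine = c("cpp", "reference"),
                              record_profiles = FALSE, validate = FALSE) {
  init <- match.arg(init)
  engine <- match.arg(engine)
  check_matrix(matrix)
  check_rule(rule)
  if (!inherits(graph, "graph_spec") && !inherits(graph, "interaction_graph"))
    stop("`graph` must be a graph_spec or an interaction_graph")
  if (!is.numeric(T_periods) || length(T_periods) != 1L || T_periods < 1 ||
      T_periods != floor(T_periods))
    stop("`T_periods` must be a positive integer (empty runs are rejected)")
  T_periods <- as.integer(T_periods)
  w <- as.integer(measure_window)
  if (length(w) != 2L || w[1] < 1L || w[2] > T_periods || w[1] > w[2])
    stop("`measure_window` must satisfy 1 <= w_start <= w_end <= T")
  n <- if (inherits(graph, "graph_spec")) graph$n else graph$n
  if (init == "half_random" && n %% 2 != 0)
    stop("half_random initialization requires an even population size")
  schedule <- normalize_schedule(schedule, T_periods, rule$p)
  structure(list(graph = graph, matrix = matrix, rule = rule,
                 T_periods = T_periods, init = init, measure_window = w,
                 seed = seed, schedule = schedule, engine = engine,
                 record_profiles = record_profiles, validate = validate),
            class = "simulation_config")
}

# Schedule -> data.frame(from, to, p) partitioning [1, T]; NULL means a
# single phase at the rule's p.
normalize_schedule <- function(schedule, T_periods, default_p) {
  if (is.null(schedule))
    return(data.frame(from = 1L, to = T_periods, p = default_p))
  if (is.list(schedule) && !is.data.frame(schedule))
    schedule <- do.call(rbind.data.frame,
                        lapply(schedule, function(x)
                          stats::setNames(as.list(x), c("from", "to", "p"))))
  if (!all(c("from", "to", "p") %in% names(schedule)))
    stop("schedule needs columns `from`, `to`, `p`")
  schedule <- schedule[order(schedule$from), , drop = FALSE]
  if (schedule$from[1] != 1 || schedule$to[nrow(schedule)] != T_periods)
    stop("schedule intervals must cover [1, T] exactly")
  if (any(schedule$to < schedule$from))
    stop("schedule interval with to < from")
  if (nrow(schedule) > 1 &&
      any(schedule$from[-1] != schedule$to[-nrow(schedule)] + 1))
    stop("schedule intervals must partition [1, T]: no gaps or overlaps")
  if (any(schedule$p < 0 | schedule$p > 1))
    stop("schedule `p` values must lie in [0, 1]")
  schedule$from <- as.integer(schedule$from)
  schedule$to <- as.integer(schedule$to)
  rownames(schedule) <- NULL
  schedule
}

#' Initialize a strategy profile
#'
#' @param n population size.
#' @param init `"half_random"` (exactly `n/2` cooperators at uniformly
#'   random positions; requires even `n`), `"all_cooperate"` or
#'   `"all_defect"`.
#' @return integer profile of length `n` (`1` = Cooperate, `0` = Defect).
#' @export
initialize_profile <- function(n, init = c("half_random", "all_cooperate", "all_defect")) {
  init <- match.arg(init)
  n <- as.integer(n)
  switch(init,
    half_random = {
      if (n %% 2 != 0) stop("half_random initialization requires an even `n`")
      prof <- integer(n)
      prof[sample.int(n, n %/% 2)] <- 1L
      prof
    },
    all_cooperate = rep(1L, n),
    all_defect = rep(0L, n)
  )
}

#' Run one simulation
#'
#' Builds the graph (period 0), initializes the strategy profile, and
#' applies `T` coalitional better-response updates, honoring any
#' collaboration schedule. Records the population share of cooperators
#' after every update and each vertex's cooperation frequency over the
#' measurement window. Deterministic given the config's seed.
#'
#' @param config a [simulation_config].
#' @return an object of class `coalition_run` with fields `coop_share`
#'   (length `T`), `per_node_coop` (length `n`), `final_profile`,
#'   `graph`, `profiles` (T-by-n matrix or `NULL`), `config` and
#'   `metadata` (seed, sizes for which no feasible coalition existed,
#'   phase table).
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("expected a `simulation_config`")
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- build_graph(config$graph)
  profile <- initialize_profile(g$n, config$init)
  rule <- config$rule
  phases <- config$schedule
  # Sizes > 1 are never drawn when every phase has p = 0, so skip their
  # (possibly expensive) enumeration in that case.
  k_enum <- if (max(phases$p) == 0) 1L else rule$k_max
  sets_by_k <- lapply(seq_len(rule$k_max), function(kk) {
    if (kk <= k_enum && kk <= g$n)
      enumerate_feasible_coalitions(g, kk, rule$feasibility)
    else matrix(integer(0), nrow = kk, ncol = 0)
  })
  feasible <- vapply(sets_by_k, function(s) ncol(s) > 0L, logical(1))
  if (k_enum < rule$k_max) feasible[(k_enum + 1):rule$k_max] <- FALSE
  size_cdf <- vapply(phases$p, function(pp)
    restricted_size_cdf(pp, rule$k_max, feasible), numeric(rule$k_max))
  size_cdf <- matrix(size_cdf, nrow = rule$k_max)
  phase_of_t <- rep.int(seq_len(nrow(phases)), phases$to - phases$from + 1L)
  pay <- flatten_matrix(config$matrix)
  tol <- matrix_tol(config$matrix)
  w <- config$measure_window
  res <- if (config$engine == "cpp") {
    run_engine_cpp(g$adj, g$n, pay, profile, config$T_periods,
                   phase_of_t - 1L, size_cdf, sets_by_k, w[1], w[2], tol,
                   config$record_profiles, config$validate)
  } else {
    run_engine_r(g, pay, profile, config$T_periods, phase_of_t, size_cdf,
                 sets_by_k, w[1], w[2], tol, config$record_profiles)
  }
  profiles <- res$profiles
  if (!is.null(profiles) && length(profiles) == 0L) profiles <- NULL
  structure(list(coop_share = as.numeric(res$coop_share),
                 per_node_coop = as.numeric(res$per_node_coop),
                 final_profile = as.integer(res$final_profile),
                 graph = g, profiles = profiles, config = config,
                 metadata = list(seed = config$seed,
                                 infeasible_sizes = which(!feasible[seq_len(k_enum)]),
                                 phases = phases,
                                 engine = config$engine)),
            class = "coalition_run")
}

#' @export
print.coalition_run <- function(x, ...) {
  w <- x$config$measure_window
  cat(sprintf(
    "coalition_run: n = %d, T = %d; window [%d, %d] mean cooperation %.3f\n",
    x$graph$n, x$config$T_periods, w[1], w[2],
    mean(x$coop_share[w[1]:w[2]])))
  invisible(x)
}

#' Mean cooperation over a window of updates
#'
#' Arithmetic mean of the population cooperation share over an inclusive
#' interval of update periods (the paper-style measurement window).
#'
#' @param run a `coalition_run`.
#' @param window inclusive `c(w_start, w_end)`; defaults to the run's
#'   configured measurement window.
#' @return a fraction in `[0, 1]`.
#' @export
window_mean_cooperation <- function(run, window = NULL) {
  if (!inherits(run, "coalition_run")) stop("expected a `coalition_run`")
  if (is.null(window)) window <- run$config$measure_window
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L ||
      window[2] > length(run$coop_share) || window[1] > window[2])
    stop("window must lie within the run: 1 <= w_start <= w_end <= T")
  mean(run$coop_share[window[1]:window[2]])
}

#' Per-vertex cooperation frequency over a window
#'
#' For each vertex, the fraction of window updates in which it played
#' Cooperate (the per-node map of the long-run experiments). The run's
#' configured window is precomputed; other windows require the run to
#' have been made with `record_profiles = TRUE`.
#'
#' @inheritParams window_mean_cooperation
#' @return numeric vector of length `n` with values in `[0, 1]`.
#' @export
per_node_cooperation <- function(run, window = NULL) {
  if (!inherits(run, "coalition_run")) stop("expected a `coalition_run`")
  if (is.null(window)) return(run$per_node_coop)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L ||
      window[2] > length(run$coop_share) || window[1] > window[2])
    stop("window must lie within the run: 1 <= w_start <= w_end <= T")
  if (identical(window, run$config$measure_window)) return(run$per_node_coop)
  if (is.null(run$profiles))
    stop("non-default windows need a run with `record_profiles = TRUE`")
  colMeans(run$profiles[window[1]:window[2], , drop = FALSE])
}

#' Sweep a (p, e) grid
#'
#' The contour-map experiment: for every combination of collaboration
#' parameter `p` and edge density `e`, run `n_graphs` independent
#' replicates — each with a freshly drawn random graph and a fresh
#' half-random initial profile — and average the window-mean cooperation
#' across replicates. The master seed deterministically spawns one child
#' seed per replicate, so every cell (and every replicate) is
#' independently reproducible.
#'
#' @param p_values,e_values grid coordinates.
#' @param n_graphs replicates per cell (the headline experiments use 50).
#' @param base_config a [simulation_config] providing everything except
#'   `p`, `e` and the per-replicate seeds; its graph must be an
#'   Erdos-Renyi or Watts-Strogatz [graph_spec].
#' @param master_seed integer master seed.
#' @return an object of class `coalition_sweep` with `cells` (data.frame
#'   `p, e, mean_coop, se, n_graphs`) and `replicates` (data.frame
#'   `p, e, replicate, seed, window_mean`).
#' @export
sweep_grid <- function(p_values, e_values, n_graphs, base_config,
                       master_seed = 1L) {
  if (!inherits(base_config, "simulation_config"))
    stop("expected a `simulation_config` as `base_config`")
  spec <- base_config$graph
  if (!inherits(spec, "graph_spec") ||
      !spec$model %in% c("erdos_renyi", "watts_strogatz"))
    stop("sweeps need a random-graph `graph_spec` in the base config")
  if (n_graphs < 1) stop("`n_graphs` must be at least 1")
  grid <- expand.grid(p = p_values, e = e_values, KEEP.OUT.ATTRS = FALSE)
  set.seed(master_seed)
  child <- matrix(sample.int(.Machine$integer.max - 1L, nrow(grid) * n_graphs),
                  nrow = nrow(grid))
  reps <- vector("list", nrow(grid))
  for (j in seq_len(nrow(grid))) {
    pj <- grid$p[j]; ej <- grid$e[j]
    spec_j <- spec
    if (spec$model == "erdos_renyi") spec_j$e <- ej
    else {
      spec_j$ws_mean_degree <- 2L * max(1L, round(ej * (spec$n - 1) / 2))
      spec_j$realized_e <- spec_j$ws_mean_degree / (spec$n - 1)
    }
    wm <- numeric(n_graphs)
    for (r in seq_len(n_graphs)) {
      cfg <- base_config
      cfg$graph <- spec_j
      cfg$rule <- coalition_rule(pj, base_config$rule$k_max,
                                 base_config$rule$feasibility)
      cfg$schedule <- data.frame(from = 1L, to = cfg$T_periods, p = pj)
      cfg$seed <- child[j, r]
      cfg$record_profiles <- FALSE
      wm[r] <- window_mean_cooperation(run_simulation(cfg))
    }
    reps[[j]] <- data.frame(p = pj, e = ej, replicate = seq_len(n_graphs),
                            seed = child[j, ], window_mean = wm)
  }
  replicates <- do.call(rbind, reps)
  cells <- do.call(rbind, lapply(reps, function(d) data.frame(
    p = d$p[1], e = d$e[1], mean_coop = mean(d$window_mean),
    se = stats::sd(d$window_mean) / sqrt(nrow(d)), n_graphs = nrow(d))))
  structure(list(cells = cells, replicates = replicates,
                 master_seed = master_seed, base_config = base_config),
            class = "coalition_sweep")
}

#' @export
print.coalition_sweep <- function(x, ...) {
  cat(sprintf("coalition_sweep: %d cells x %d replicates (master seed %d)\n",
              nrow(x$cells), x$cells$n_graphs[1], x$master_seed))
  print(utils::head(x$cells, 10))
  if (nrow(x$cells) > 10) cat("...\n")
  invisible(x)
}

#' Deterministic fixture suite for tests and examples
#'
#' Small graphs and strategy profiles exercising the model's decision
#' boundaries: an isolated triangle with a tail (the canonical profitable
#' all-Defect coalition), path/star/cycle/complete graphs, a small random
#' graph, and a degree-4 defector with exactly one coalition neighbor —
#' the case whose closed-form gain `(b - c) d + b s` is 0 at
#' `b = 4, c = 5` (the switch is a coalitional better response) but -1 at
#' `b = 3, c = 4` (blocked).
#'
#' @param seed integer seed; the same seed always regenerates the
#'   identical bundle.
#' @return a named list of fixtures; graph-bearing entries carry the
#'   graph, a profile and, where relevant, the coalition of interest.
#' @export
generate_fixture_suite <- function(seed = 1L) {
  set.seed(seed)
  # isolated triangle {1,2,3} + path tail 4-5-6-7 + isolated vertex 8
  tri_tail <- interaction_graph(8, rbind(c(1, 2), c(1, 3), c(2, 3),
                                         c(4, 5), c(5, 6), c(6, 7)))
  # vertex 1 has degree 4 (neighbors 2..5); coalition {1, 2}; vertex 2 has
  # a pendant neighbor 6 so the coalition is connected with s = 1 for 1.
  thresh <- interaction_graph(6, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                                       c(2, 6)))
  list(
    triangle_tail = list(graph = tri_tail, profile = rep(0L, 8),
                         coalition = c(1L, 2L, 3L)),
    threshold_d4_s1 = list(graph = thresh, profile = rep(0L, 6),
                           coalition = c(1L, 2L), d = 4L, s = 1L),
    path5 = list(graph = interaction_graph(5, cbind(1:4, 2:5)),
                 profile = c(1L, 0L, 1L, 0L, 1L)),
    star6 = list(graph = interaction_graph(6, cbind(rep(1L, 5), 2:6)),
                 profile = c(0L, rep(1L, 5))),
    cycle6 = list(graph = interaction_graph(6, cbind(1:6, c(2:6, 1L))),
                  profile = rep(c(1L, 0L), 3)),
    complete5 = list(graph = interaction_graph(5, t(utils::combn(5, 2))),
                     profile = rep(0L, 5)),
    random8 = list(graph = generate_erdos_renyi(8, 0.4),
                   profile = initialize_profile(8, "half_random"))
  )
}
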