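test_that("coalition size is 1 + Binomial(k_max - 1, p)", {
  expect_true(all(sample_coalition_size(coalition_rule(0), 500) == 1L))
  expect_true(all(sample_coalition_size(coalition_rule(1), 500) == 5L))
  set.seed(21)
  draws <- sample_coalition_size(coalition_rule(0.5), 20000)
  expect_true(all(draws %in% 1:5))
  # P(k = 3) = choose(4, 2) * 0.5^4 = 0.375
  expect_lt(abs(mean(draws == 3) - 0.375), 0.02)
  expect_error(coalition_rule(1.5), "\\[0, 1\\]")
})

test_that("coalition sampling is uniform over enumerated feasible sets", {
  path4 <- interaction_graph(4, cbind(1:3, 2:4))
  set.seed(22)
  draws <- replicate(6000, paste(sample_coalition(path4, 2, "connected"),
                                 collapse = "-"))
  tab <- table(draws)
  expect_identical(sort(names(tab)), c("1-2", "2-3", "3-4"))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  # complete-graph singletons: uniform over individuals
  k5 <- interaction_graph(5, t(utils::combn(5, 2)))
  singles <- replicate(2000, sample_coalition(k5, 1, "connected"))
  expect_identical(sort(unique(singles)), 1:5)
})

test_that("clique-mode sampling always yields cliques; infeasible sizes fall back", {
  set.seed(23)
  g <- generate_erdos_renyi(12, 0.35)
  for (i in 1:50) {
    S <- sample_coalition(g, sample(1:3, 1), "clique")
    expect_true(is_clique(g, S))
  }
  # matching graph: components of size 2, so no connected triples exist
  m <- interaction_graph(6, rbind(c(1, 2), c(3, 4), c(5, 6)))
  S <- sample_coalition(m, 3, "connected")
  expect_lte(length(S), 2L)
  S2 <- sample_coalition(m, 3, "connected", rule = coalition_rule(0.9))
  expect_true(length(S2) %in% 1:2)
})

test_that("weak-improvement predicate follows the stated comparison semantics", {
  M <- benchmark_matrix()
  # lone defector with neighbors never weakly improves by cooperating
  star <- interaction_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_false(joint_switch_weakly_improves(star, M, rep(0L, 4), 1, 1L))
  # all-Defect isolated triangle: each member 0 -> 2 * (2b - c) = 4
  fx <- generate_fixture_suite(1)
  tri <- fx$triangle_tail
  expect_true(joint_switch_weakly_improves(tri$graph, M, tri$profile,
                                           tri$coalition, 1L))
  # defector with d = 3, s = 1: delta = (b - c) * 3 + b = 0, weakly improving
  g31 <- interaction_graph(5, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5)))
  expect_true(joint_switch_weakly_improves(g31, M, rep(0L, 5), c(1, 2), 1L))
  expect_equal(defector_gain_closed_form(3, 4, 3, 1), 0)
})

test_that("closed-form defector gain matches its worked cases and domain", {
  expect_equal(defector_gain_closed_form(4, 5, 4, 1), 0)
  expect_equal(defector_gain_closed_form(3, 4, 4, 1), -1)
  for (d in 1:5)
    expect_equal(defector_gain_closed_form(3, 4, d, d), (2 * 3 - 4) * d)
  expect_error(defector_gain_closed_form(3, 4, 2, 3), "0 <= s <= d")
  expect_error(defector_gain_closed_form(3, 7, 2, 1), "PD-form")
})

test_that("closed-form gain equals brute-force payoff differencing", {
  set.seed(24)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    edges <- random_small_graph(n)
    g <- interaction_graph(n, edges)
    bc <- list(c(3, 4), c(4, 5), c(2, 3))[[sample(3, 1)]]
    M <- pd_matrix_from_benefit_cost(bc[1], bc[2])
    profile <- sample(0:1, n, replace = TRUE)
    k <- sample(2:4, 1)
    sets <- enumerate_feasible_coalitions(g, min(k, n), "connected")
    if (ncol(sets) == 0) next
    S <- sets[, sample(ncol(sets), 1)]
    for (v in S[profile[S] == 0L]) {
      nb <- g$adj[[v]]
      d <- length(nb)
      s <- sum(nb %in% S & profile[nb] == 0L)  # neighbors switching D -> C
      expect_equal(defector_gain_closed_form(bc[1], bc[2], d, s),
                   oracle_switch_delta(edges, M, profile, S, v, 1L))
    }
  }
})

test_that("the better response applies all-C, all-D or no-op per the tie rule", {
  M <- benchmark_matrix()
  fx <- generate_fixture_suite(1)
  tri <- fx$triangle_tail
  # all-D isolated triangle: both options weakly improve; coin flip
  set.seed(25)
  outcomes <- replicate(4000, {
    p2 <- apply_coalitional_better_response(tri$graph, M, tri$profile,
                                            tri$coalition)
    all(p2[tri$coalition] == 1L)
  })
  expect_gt(mean(outcomes), 0.45)
  expect_lt(mean(outcomes), 0.55)
  # non-members never change
  p2 <- apply_coalitional_better_response(tri$graph, M, tri$profile,
                                          tri$coalition)
  expect_identical(p2[4:8], tri$profile[4:8])
  # mixed pair where both uniform switches hurt the defector: no-op
  g <- interaction_graph(7, rbind(c(1, 2), c(2, 3), c(2, 4), c(2, 5), c(2, 6)))
  prof <- c(1L, 0L, 0L, 0L, 0L, 0L, 0L)  # 1 cooperates, hub 2 defects
  expect_identical(apply_coalitional_better_response(g, M, prof, c(1, 2)), prof)
  # threshold case: the same joint switch passes at b=4,c=5, blocked at b=3,c=4
  th <- fx$threshold_d4_s1
  expect_true(joint_switch_weakly_improves(th$graph, pd_matrix_from_benefit_cost(4, 5),
                                           th$profile, th$coalition, 1L))
  expect_false(joint_switch_weakly_improves(th$graph, benchmark_matrix(),
                                            th$profile, th$coalition, 1L))
})

test_that("completely indifferent coalitions resolve to Defect", {
  M <- benchmark_matrix()
  g <- interaction_graph(3, rbind(c(2, 3)))   # vertex 1 isolated
  expect_identical(apply_coalitional_better_response(g, M, c(1L, 0L, 0L), 1)[1], 0L)
  expect_identical(apply_coalitional_better_response(g, M, c(0L, 0L, 0L), 1)[1], 0L)
})

test_that("purely individualistic updating never gains cooperators and absorbs at all-D", {
  M <- benchmark_matrix()
  rule0 <- coalition_rule(0)
  set.seed(26)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    g <- interaction_graph(n, random_small_graph(n))
    prof <- sample(0:1, n, replace = TRUE)
    for (step in 1:30) {
      nxt <- update_step(g, M, prof, rule0)
      expect_lte(sum(nxt), sum(prof))
      prof <- nxt
    }
    # all-Defect is absorbing under singleton updates
    alld <- rep(0L, n)
    for (step in 1:20)
      expect_identical(update_step(g, M, alld, rule0), alld)
  }
})

test_that("every update weakly improves the members' own payoffs", {
  cfg <- simulation_config(graph_spec("erdos_renyi", 16, 0.25),
                           benchmark_matrix(), coalition_rule(0.6),
                           T_periods = 800, measure_window = c(401, 800),
                           seed = 27, validate = TRUE)
  expect_no_error(run_simulation(cfg))
  cfg$rule <- coalition_rule(0.6, feasibility = "clique")
  expect_no_error(run_simulation(cfg))
})

test_that("the C++ engine and the R reference engine produce identical trajectories", {
  M <- benchmark_matrix()
  for (seed in c(31, 32)) {
    cfg <- simulation_config(graph_spec("erdos_renyi", 14, 0.3), M,
                             coalition_rule(0.5), T_periods = 400,
                             measure_window = c(201, 400), seed = seed,
                             record_profiles = TRUE)
    ref <- cfg; ref$engine <- "reference"
    a <- run_simulation(cfg)
    b <- run_simulation(ref)
    expect_identical(a$coop_share, b$coop_share)
    expect_identical(a$final_profile, b$final_profile)
    expect_equal(a$per_node_coop, b$per_node_coop)
    expect_identical(unname(a$profiles), unname(b$profiles))
  }
  # schedules too
  sched <- data.frame(from = c(1, 101, 201), to = c(100, 200, 300),
                      p = c(0.7, 0, 0.7))
  cfg <- simulation_config(graph_spec("erdos_renyi", 12, 0.2), M,
                           coalition_rule(0.7), T_periods = 300,
                           measure_window = c(201, 300), seed = 33,
                           schedule = sched)
  ref <- cfg; ref$engine <- "reference"
  expect_identical(run_simulation(cfg)$coop_share,
                   run_simulation(ref)$coop_share)
})
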