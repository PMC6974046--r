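#' Coalition selection rule
#'
#' Bundles the parameters governing which coalition updates each period:
#' the maximum coalition size `k_max` (the model's k-bar, default 5), the
#' feasibility notion (connected induced subgraph, or clique for the
#' robustness treatment), and the collaboration parameter `p`. The size of
#' the updating coalition is `1 + Binomial(k_max - 1, p)`, so `p = 0`
#' yields purely individualistic updating and `p = 1` always selects
#' coalitions of maximal size.
#'
#' @param p collaboration parameter in `[0, 1]`.
#' @param k_max maximum coalition size (at least 1).
#' @param feasibility `"connected"` or `"clique"`.
#' @return an object of class `coalition_rule`.
#' @export
coalition_rule <- function(p, k_max = 5, feasibility = c("connected", "clique")) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("collaboration parameter `p` must lie in [0, 1]")
  if (!is.numeric(k_max) || length(k_max) != 1L || k_max < 1 || k_max != floor(k_max))
    stop("`k_max` must be a positive integer")
  feasibility <- match.arg(feasibility)
  structure(list(p = p, k_max = as.integer(k_max), feasibility = feasibility),
            class = "coalition_rule")
}

#' @export
print.coalition_rule <- function(x, ...) {
  cat(sprintf("coalition_rule: p = %g, k_max = %d, feasibility = %s\n",
              x$p, x$k_max, x$feasibility))
  invisible(x)
}

check_rule <- function(rule) {
  if (!inherits(rule, "coalition_rule"))
    stop("expected a `coalition_rule` object")
  rule
}

#' Draw a coalition size
#'
#' The probability that the updating coalition contains `k` individuals is
#' the probability of `k - 1` successes in `Binomial(k_max - 1, p)`, so
#' the support is exactly `1..k_max`.
#'
#' @param rule a [coalition_rule].
#' @param n_draws number of independent sizes to draw.
#' @return integer vector of sizes in `1..k_max`.
#' @export
sample_coalition_size <- function(rule, n_draws = 1) {
  check_rule(rule)
  1L + stats::rbinom(n_draws, rule$k_max - 1L, rule$p)
}

# Restricted size distribution: pmf of 1 + Binomial(k_max - 1, p) renormalized
# to the feasible sizes (those with at least one feasible coalition). Size 1
# is always feasible on a nonempty vertex set. If the restriction carries no
# probability mass (e.g. p = 1 but no feasible coalition of size k_max), all
# mass is placed on the largest feasible size. Returns the CDF (length k_max,
# last entry exactly 1) used by single-uniform inversion in both engines.
restricted_size_cdf <- function(p, k_max, feasible) {
  pmf <- stats::dbinom(0:(k_max - 1L), k_max - 1L, p)
  pmf[!feasible] <- 0
  tot <- sum(pmf)
  if (tot <= 0) {
    pmf <- rep(0, k_max)
    pmf[max(which(feasible))] <- 1
  } else {
    pmf <- pmf / tot
  }
  cdf <- cumsum(pmf)
  cdf[length(cdf)] <- 1
  cdf
}

# Single-uniform inverse-CDF draw; consumes exactly one runif(1).
draw_from_cdf <- function(cdf) {
  u <- stats::runif(1)
  for (k in seq_along(cdf)) if (u < cdf[k]) return(k)
  length(cdf)
}

# Uniform index in 1..m from one runif(1); mirrors the C++ engine.
draw_index <- function(m) {
  idx <- 1L + as.integer(floor(stats::runif(1) * m))
  min(idx, m)
}

#' Draw a feasible coalition of a given size
#'
#' Uniform draw over the exhaustively enumerated feasible coalitions of
#' size `k` (see [enumerate_feasible_coalitions()]). If no feasible
#' coalition of size `k` exists (possible on sparse or disconnected
#' graphs), the size is redrawn from the rule's size distribution
#' restricted and renormalized to feasible sizes when a `rule` is
#' supplied; otherwise the largest feasible size below `k` is used.
#' Singletons are always feasible, so both fallbacks terminate.
#'
#' @param g an [interaction_graph].
#' @param k requested coalition size.
#' @param mode `"connected"` or `"clique"`.
#' @param rule optional [coalition_rule] used for the infeasible-size
#'   fallback.
#' @return integer vector of member vertex ids (sorted).
#' @export
sample_coalition <- function(g, k, mode = c("connected", "clique"), rule = NULL) {
  check_graph(g)
  mode <- match.arg(mode)
  sets <- enumerate_feasible_coalitions(g, k, mode)
  if (ncol(sets) == 0L) {
    if (!is.null(rule)) {
      check_rule(rule)
      k <- draw_from_cdf(restricted_size_cdf(rule$p, rule$k_max,
                                             feasible_sizes(g, rule)))
    } else {
      k <- max(which(vapply(seq_len(k), function(kk)
        ncol(enumerate_feasible_coalitions(g, kk, mode)) > 0L, logical(1))))
    }
    sets <- enumerate_feasible_coalitions(g, k, mode)
  }
  sets[, draw_index(ncol(sets))]
}

# Which sizes 1..k_max admit at least one feasible coalition (sizes above
# n never do).
feasible_sizes <- function(g, rule) {
  vapply(seq_len(rule$k_max), function(kk)
    kk <= g$n && ncol(enumerate_feasible_coalitions(g, kk, rule$feasibility)) > 0L,
    logical(1))
}

#' Does a uniform joint switch weakly improve every member?
#'
#' Evaluates the hypothetical profile in which every member of the
#' coalition plays `target` while all non-members keep their current
#' strategies, and compares each member's total payoff with its current
#' value. Members already playing `target` still contribute comparisons:
#' they can gain (or lose) from their neighbors' switches.
#'
#' @param g an [interaction_graph].
#' @param M a `payoff_matrix`.
#' @param profile integer strategy profile.
#' @param S member vertex ids (a feasible coalition).
#' @param target `1` (Cooperate) or `0` (Defect).
#' @return `TRUE` iff every member's payoff after the joint switch is at
#'   least its current payoff.
#' @export
joint_switch_weakly_improves <- function(g, M, profile, S, target) {
  check_graph(g)
  check_matrix(M)
  profile <- check_profile(g, profile)
  S <- check_vertices(g, S)
  if (!target %in% c(0L, 1L)) stop("`target` must be 0 (Defect) or 1 (Cooperate)")
  pay <- flatten_matrix(M)
  tol <- matrix_tol(M)
  cur <- member_payoffs(g, pay, profile, S, own = profile[S], target = NA)
  new <- member_payoffs(g, pay, profile, S, own = rep(target, length(S)),
                        target = target)
  all(new - cur >= -tol)
}

#' Closed-form gain of a defector from an all-to-Cooperate switch
#'
#' For benefit/cost payoffs, a member currently playing Defect, with
#' degree `d` and `s` neighbors that switch from Defect to Cooperate as
#' part of the joint move, changes its total payoff by exactly
#' \deqn{(b - c)\,d + b\,s.}
#' For the canonical case of a coalition whose members all currently
#' defect, `s` is simply the member's number of neighbors inside the
#' coalition, and the change is independent of the current strategies of
#' everyone else (each non-switching neighbor contributes `b - c`
#' whatever it plays). The switch is
#' weakly profitable for that member iff `s / d >= (c - b) / b`. This is
#' the algebraic heart of why sparse graphs favor cooperation: members of
#' small dense clusters have a high fraction of their neighbors inside the
#' coalition. Used as an independent oracle against brute-force payoff
#' differencing.
#'
#' @param b,c benefit and cost (PD form, `2b > c > b > 0`).
#' @param d degree of the member.
#' @param s number of its neighbors switching from Defect to Cooperate
#'   alongside it, `0 <= s <= d`.
#' @return the payoff change, `(b - c) * d + b * s`.
#' @export
defector_gain_closed_form <- function(b, c, d, s) {
  if (!(b > 0 && c > b && 2 * b > c))
    stop("payoffs must be PD-form: 2b > c > b > 0")
  if (any(s < 0) || any(d < 0) || any(s > d))
    stop("`s` must satisfy 0 <= s <= d")
  (b - c) * d + b * s
}

# Shared decision kernel. Returns the applied target: 1 (all-Cooperate),
# 0 (all-Defect) or -1 (no change). Consumes one runif(1) iff both options
# weakly improve and the coalition is not completely indifferent.
cbr_decide <- function(g, pay, tol, profile, S) {
  cur <- member_payoffs(g, pay, profile, S, own = profile[S], target = NA)
  dC <- member_payoffs(g, pay, profile, S, own = rep(1L, length(S)), target = 1L) - cur
  dD <- member_payoffs(g, pay, profile, S, own = rep(0L, length(S)), target = 0L) - cur
  weakC <- all(dC >= -tol)
  weakD <- all(dD >= -tol)
  if (weakC && weakD) {
    if (all(abs(dC) <= tol) && all(abs(dD) <= tol)) {
      0L   # completely indifferent: adopt Defect, the dominant strategy
    } else if (stats::runif(1) < 0.5) 1L else 0L
  } else if (weakC) 1L
  else if (weakD) 0L
  else -1L
}

#' Apply a coalitional better response
#'
#' The updating coalition considers the two uniform joint switches:
#' (i) every member plays Cooperate, (ii) every member plays Defect, in
#' both cases holding all non-members fixed. If only one of the two
#' weakly improves every member's payoff, it is applied; if both do, one
#' of the two outcomes is chosen with equal probability; if neither does,
#' every member keeps its current strategy. For a homogeneous coalition
#' the option matching the status quo holds trivially, which is what
#' allows, e.g., an all-Defect cluster to move jointly to Cooperate with
#' probability one half when that switch profits all members.
#'
#' One refinement to the coin flip: when the coalition is *completely
#' indifferent* — no member's payoff differs across staying, all-Cooperate
#' and all-Defect (e.g. an isolated vertex updating alone) — the coalition
#' adopts Defect, the weakly dominant strategy, rather than randomizing.
#' Without this, isolated vertices would flicker between strategies
#' forever and purely individualistic updating (`p = 0`) would not drive
#' cooperation to zero on sparse graphs.
#'
#' @inheritParams joint_switch_weakly_improves
#' @return the updated strategy profile; differs from `profile` only on
#'   `S`.
#' @export
apply_coalitional_better_response <- function(g, M, profile, S) {
  check_graph(g)
  check_matrix(M)
  profile <- check_profile(g, profile)
  S <- check_vertices(g, S)
  target <- cbr_decide(g, flatten_matrix(M), matrix_tol(M), profile, S)
  if (target >= 0L) profile[S] <- target
  profile
}

#' One period of the dynamics
#'
#' Composes the three stages of a single update: draw a coalition size
#' from `1 + Binomial(k_max - 1, p)` (restricted to sizes for which a
#' feasible coalition exists), draw a coalition uniformly among the
#' feasible sets of that size, and apply the coalitional better response.
#' Exactly one coalition acts per period.
#'
#' @param g an [interaction_graph].
#' @param M a `payoff_matrix`.
#' @param profile integer strategy profile.
#' @param rule a [coalition_rule].
#' @return the updated strategy profile.
#' @export
update_step <- function(g, M, profile, rule) {
  check_graph(g)
  check_matrix(M)
  check_rule(rule)
  profile <- check_profile(g, profile)
  cdf <- restricted_size_cdf(rule$p, rule$k_max, feasible_sizes(g, rule))
  step_reference(g, flatten_matrix(M), matrix_tol(M), profile, rule, cdf)
}

# One period, reference implementation; consumes RNG draws in exactly the
# engine's order (size uniform, index uniform, optional coin).
step_reference <- function(g, pay, tol, profile, rule, cdf) {
  k <- draw_from_cdf(cdf)
  sets <- enumerate_feasible_coalitions(g, k, rule$feasibility)
  S <- sets[, draw_index(ncol(sets))]
  target <- cbr_decide(g, pay, tol, profile, S)
  if (target >= 0L) profile[S] <- target
  profile
}

# Pure-R engine mirroring run_engine_cpp draw for draw; used as the dual
# route in trajectory-equality tests and available via
# run_simulation(engine = "reference").
run_engine_r <- function(g, pay, init, T_periods, phase_of_t, size_cdf,
                         sets_by_k, wstart, wend, tol, record_profiles = FALSE) {
  profile <- init
  n <- g$n
  coop_share <- numeric(T_periods)
  node_count <- numeric(n)
  profiles <- if (record_profiles) matrix(0L, T_periods, n) else NULL
  for (t in seq_len(T_periods)) {
    cdf <- size_cdf[, phase_of_t[t]]
    k <- draw_from_cdf(cdf)
    sets <- sets_by_k[[k]]
    S <- sets[, draw_index(ncol(sets))]
    target <- cbr_decide(g, pay, tol, profile, S)
    if (target >= 0L) profile[S] <- target
    coop_share[t] <- sum(profile) / n
    if (t >= wstart && t <= wend) node_count <- node_count + profile
    if (record_profiles) profiles[t, ] <- profile
  }
  list(coop_share = coop_share,
       per_node_coop = node_count / (wend - wstart + 1),
       final_profile = profile,
       profiles = profiles)
}
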