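#' Prisoner's dilemma payoff matrices
#'
#' The stage game is a two-strategy game played pairwise along every edge
#' of the interaction graph. In the benefit/cost form, playing Cooperate
#' confers a benefit `b` on both interactants at a cost `c` to the
#' cooperator, giving interaction payoffs
#' \deqn{(C,C) \to 2b - c,\quad (C,D) \to b - c,\quad (D,C) \to b,\quad (D,D) \to 0,}
#' a prisoner's dilemma whenever `2b > c > b > 0` (so mutual cooperation
#' beats mutual defection, but Defect strictly dominates for a lone
#' updater with at least one neighbor).
#'
#' Strategies are coded throughout the package as integers:
#' `1 = Cooperate`, `0 = Defect`. A strategy profile is an integer vector
#' of length `n` in this coding.
#'
#' @param b benefit of cooperation, received by both interactants.
#' @param c cost of cooperation, paid by the cooperator; must satisfy
#'   `2b > c > b > 0`.
#' @return a `payoff_matrix`: a 2x2 numeric matrix with dimnames
#'   `C`/`D` (rows: own strategy; columns: other's strategy) and, for the
#'   benefit/cost form, attributes `b` and `c`.
#' @examples
#' pd_matrix_from_benefit_cost(3, 4)   # the benchmark treatment
#' @export
pd_matrix_from_benefit_cost <- function(b, c) {
  if (!is.numeric(b) || !is.numeric(c) || length(b) != 1L || length(c) != 1L)
    stop("`b` and `c` must be single numbers")
  if (!(b > 0)) stop("payoff constraint violated: b > 0 fails")
  if (!(c > b)) stop("payoff constraint violated: c > b fails")
  if (!(2 * b > c)) stop("payoff constraint violated: 2b > c fails")
  M <- matrix_from_entries(2 * b - c, b - c, b, 0)
  attr(M, "b") <- b
  attr(M, "c") <- c
  M
}

#' Build a payoff matrix from its four entries
#'
#' General constructor for arbitrary 2x2 interaction payoffs, e.g. the
#' classic Axelrod-Hamilton values `(3, 0, 5, 1)`.
#'
#' @param rcc payoff of Cooperate against Cooperate.
#' @param rcd payoff of Cooperate against Defect.
#' @param rdc payoff of Defect against Cooperate.
#' @param rdd payoff of Defect against Defect.
#' @return a `payoff_matrix`.
#' @export
matrix_from_entries <- function(rcc, rcd, rdc, rdd) {
  M <- matrix(c(rcc, rcd, rdc, rdd), nrow = 2, byrow = TRUE,
              dimnames = list(own = c("C", "D"), other = c("C", "D")))
  class(M) <- c("payoff_matrix", class(M))
  M
}

#' @export
print.payoff_matrix <- function(x, ...) {
  b <- attr(x, "b"); c <- attr(x, "c")
  if (!is.null(b)) cat(sprintf("payoff_matrix (b = %g, c = %g)\n", b, c))
  else cat("payoff_matrix\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

check_matrix <- function(M) {
  if (!inherits(M, "payoff_matrix"))
    stop("expected a `payoff_matrix` (see pd_matrix_from_benefit_cost)")
  M
}

# Flatten to the engine layout pay[own * 2 + other + 1], own/other in
# {0 = D, 1 = C}.
flatten_matrix <- function(M) {
  c(M["D", "D"], M["D", "C"], M["C", "D"], M["C", "C"])
}

# Comparison tolerance: exact for all-integer payoffs, 1e-9 otherwise.
matrix_tol <- function(M) {
  if (all(unclass(M) == round(unclass(M)))) 0 else 1e-9
}

check_profile <- function(g, profile) {
  profile <- as.integer(profile)
  if (length(profile) != g$n)
    stop("strategy profile length must equal the number of vertices")
  if (anyNA(profile) || !all(profile %in% c(0L, 1L)))
    stop("strategies must be coded 0 (Defect) or 1 (Cooperate)")
  profile
}

#' Total payoff of an individual
#'
#' The sum of pairwise interaction payoffs against every neighbor on the
#' graph, under the current strategy profile. Isolated vertices receive 0.
#' Payoffs are flows: they are recomputed from the current profile at
#' every evaluation, with no accumulation across periods.
#'
#' @param g an [interaction_graph].
#' @param M a `payoff_matrix`.
#' @param profile integer strategy profile (`1` = Cooperate, `0` = Defect).
#' @param i vertex id.
#' @return a number.
#' @examples
#' g <- interaction_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
#' M <- pd_matrix_from_benefit_cost(3, 4)
#' total_payoff(g, M, c(1, 1, 1, 0), 1)  # 2 + 2 - 1 = 3
#' @export
total_payoff <- function(g, M, profile, i) {
  check_graph(g)
  check_matrix(M)
  profile <- check_profile(g, profile)
  i <- check_vertices(g, i)
  if (length(i) != 1L) stop("`i` must be a single vertex")
  nb <- g$adj[[i]]
  if (length(nb) == 0L) return(0)
  pay <- flatten_matrix(M)
  sum(pay[profile[i] * 2L + profile[nb] + 1L])
}

# Payoffs of the members of S when each plays own[r] and the coalition's
# neighbors inside S play `target` (NA = no override: everyone keeps
# `profile`, giving current payoffs). Mirrors the engine's evaluation.
member_payoffs <- function(g, pay, profile, S, own, target = NA) {
  in_s <- logical(g$n)
  in_s[S] <- TRUE
  vapply(seq_along(S), function(r) {
    v <- S[r]
    nb <- g$adj[[v]]
    if (length(nb) == 0L) return(0)
    other <- profile[nb]
    if (!is.na(target)) other[in_s[nb]] <- target
    sum(pay[own[r] * 2L + other + 1L])
  }, numeric(1))
}
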