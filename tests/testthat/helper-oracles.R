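# Independent oracles used across the suite. These re-derive quantities by
# brute force (policy enumeration, quadrature, direct simulation) and stay
# independent of the code paths they check.

# Exhaustive policy search: evaluate every stationary action map exactly and
# return the best cost vector (state-wise minimum is attained by one policy).
brute_force_optimal <- function(P, problem) {
  S <- problem$S
  best_J <- rep(Inf, S)
  best_actions <- integer(S)
  for (code in 0:(2^S - 1)) {
    actions <- as.integer((code %/% 2^(seq_len(S) - 1)) %% 2)
    J <- policy_evaluation_exact(P, actions, problem)
    if (mean(J) < mean(best_J)) {
      best_J <- J
      best_actions <- actions
    }
  }
  list(actions = best_actions, J = best_J)
}

# Random row-stochastic matrix.
random_stochastic <- function(S, seed) {
  set.seed(seed)
  P <- matrix(stats::rexp(S * S), S, S)
  P / rowSums(P)
}

# Random cost table r(i, j, c) as a function, from a fixed seed.
random_cost_fn <- function(S, seed) {
  set.seed(seed)
  tbl <- array(stats::runif(S * S * 2, 0, 10), dim = c(S, S, 2))
  function(i, j, c) tbl[i + 1, j + 1, c + 1]
}

# Monte-Carlo mean hitting time of `target` (0-based states) from state s0.
mc_hitting_time <- function(P, s0, target, n_rep, max_steps = 10000) {
  S <- nrow(P)
  times <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    s <- s0
    for (t in seq_len(max_steps)) {
      s <- sample.int(S, 1, prob = P[s + 1, ]) - 1L
      if (s %in% target) { times[r] <- t; break }
    }
    if (times[r] == 0) times[r] <- max_steps
  }
  times
}

# Gauss-style quadrature of g(theta) against a Beta(a, b) density on a fine
# midpoint grid (independent of any package sampling).
beta_quadrature <- function(g, a, b, n_grid = 1001) {
  mid <- (seq_len(n_grid) - 0.5) / n_grid
  w <- stats::dbeta(mid, a, b) / n_grid
  vals <- vapply(mid, g, numeric(1))
  sum(w * vals) / sum(w)
}

# Small 2-gene CPM set with simple regulator structure (each gene reads both
# genes), entries chosen away from ties.
two_gene_cpms <- function(seed = 42) {
  set.seed(seed)
  regs <- list(c(1L, 2L), c(1L, 2L))
  mats <- lapply(1:2, function(i) {
    c0 <- stats::runif(4, 0.1, 0.9)
    cbind(c0, 1 - c0, deparse.level = 0)
  })
  cpm_set(mats, regs)
}

two_gene_problem <- function(zeta = 0.2) {
  control_problem(2, control_gene = 2, undesirable = c(0, 1), zeta = zeta)
}
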