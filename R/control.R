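#' Stationary control problem for a Markovian network
#'
#' Control flips a designated control gene: under action `c = 1` the chain
#' leaves from the state with gene `g` flipped, under `c = 0` it evolves
#' freely. Costs `r(i, j, c)` are accrued per transition and discounted by
#' `zeta`; undesirable states carry higher cost. The default cost table is
#' 6 / 5 / 1 / 0 for (target undesirable, action) = (yes, 1) / (yes, 0) /
#' (no, 1) / (no, 0).
#'
#' @param n gene count.
#' @param control_gene 1-based index of the gene flipped by the control input.
#' @param undesirable vector of decimal states forming the undesirable set U.
#' @param zeta discount factor in (0, 1) (default 0.2).
#' @param cost cost function `function(i, j, c)` over decimal states and the
#'   binary action, or `NULL` for the default table.
#' @return an object of class `control_problem`.
#' @export
control_problem <- function(n, control_gene, undesirable, zeta = 0.2, cost = NULL) {
  S <- 2^n
  if (zeta <= 0 || zeta >= 1) stop("discount factor must lie in (0, 1)", call. = FALSE)
  if (control_gene < 1 || control_gene > n) stop("invalid control gene", call. = FALSE)
  undesirable <- sort(unique(as.integer(undesirable)))
  if (any(undesirable < 0) || any(undesirable >= S)) {
    stop("undesirable states out of range", call. = FALSE)
  }
  if (length(undesirable) == 0 || length(undesirable) == S) {
    stop("undesirable set must be a nonempty strict subset of the state space",
         call. = FALSE)
  }
  pr <- structure(
    list(n = n, S = S, control_gene = as.integer(control_gene),
         undesirable = undesirable,
         desirable = setdiff(0:(S - 1), undesirable),
         zeta = zeta, cost = cost),
    class = "control_problem"
  )
  pr
}

#' @export
print.control_problem <- function(x, ...) {
  cat(sprintf(
    "Control problem: %d genes (%d states), control gene %d, zeta = %g, |U| = %d\n",
    x$n, x$S, x$control_gene, x$zeta, length(x$undesirable)))
  invisible(x)
}

#' Default transition cost
#'
#' @param i,j source and target decimal states.
#' @param c binary action.
#' @param undesirable undesirable state set.
#' @return cost 6 (`j` undesirable, act), 5 (`j` undesirable, no action),
#'   1 (`j` desirable, act) or 0.
#' @export
default_cost <- function(i, j, c, undesirable) {
  5 * (j %in% undesirable) + 1 * (c == 1)
}

# S x S cost matrix for a fixed action; vectorized over the default table,
# falls back to the user cost function elementwise.
cost_matrix <- function(problem, action) {
  S <- problem$S
  states <- 0:(S - 1)
  if (is.null(problem$cost)) {
    base <- 5 * (states %in% problem$undesirable) + 1 * (action == 1)
    matrix(base, S, S, byrow = TRUE)
  } else {
    outer(states, states, Vectorize(function(i, j) problem$cost(i, j, action)))
  }
}

#' Controlled transition probability matrix
#'
#' Under `c = 1` the chain transitions as if started from the flipped state:
#' row `i` is replaced by row `i` with the control gene's bit flipped. `c = 0`
#' leaves the matrix unchanged.
#'
#' @param P uncontrolled TPM.
#' @param g control gene (1-based).
#' @param c binary action.
#' @return the controlled TPM.
#' @export
controlled_tpm <- function(P, g, c) {
  if (c == 0) return(P)
  S <- nrow(P)
  n <- as.integer(round(log2(S)))
  flip <- flip_gene(0:(S - 1), g, n)
  P[flip + 1L, , drop = FALSE]
}

# Precompute the two controlled TPMs and expected immediate costs.
mdp_tables <- function(P, problem) {
  g <- problem$control_gene
  P0 <- P
  P1 <- controlled_tpm(P, g, 1)
  R0 <- rowSums(P0 * cost_matrix(problem, 0))
  R1 <- rowSums(P1 * cost_matrix(problem, 1))
  list(P0 = P0, P1 = P1, R0 = R0, R1 = R1)
}

#' Optimal stationary policy by value iteration
#'
#' Iterates the Bellman operator
#' \eqn{TJ(i) = \min_c \sum_j P_{ij}(c) (r(i,j,c) + \zeta J(j))} from
#' \eqn{J_0 = 0}. With `iterations = NULL` the iteration runs to convergence
#' (sup-norm residual below `tol`); a finite `iterations` performs exactly
#' that many applications of `T` (truncated value iteration). The returned
#' greedy policy attains the minimum at the last application; exact ties break
#' to `c = 0` (no intervention).
#'
#' Applied to an effective TPM this returns the intrinsically Bayesian robust
#' (IBR) policy, the minimizer of the prior-averaged expected discounted cost
#' (see [ibr_policy()]).
#'
#' @param P TPM (or ETPM).
#' @param problem a [control_problem()].
#' @param iterations number of Bellman applications, or `NULL` to converge.
#' @param tol convergence tolerance on the Bellman residual.
#' @param max_iterations safety cap when converging.
#' @return an object of class `grn_policy` with elements `actions` (binary,
#'   by state), `J` (cost-to-go vector), `residual`, `iterations`.
#' @export
value_iteration <- function(P, problem, iterations = NULL, tol = 1e-10,
                            max_iterations = 10000) {
  stopifnot(inherits(problem, "control_problem"))
  tb <- mdp_tables(P, problem)
  S <- problem$S
  zeta <- problem$zeta
  J <- numeric(S)
  it <- 0
  repeat {
    Q0 <- tb$R0 + zeta * as.numeric(tb$P0 %*% J)
    Q1 <- tb$R1 + zeta * as.numeric(tb$P1 %*% J)
    Jn <- pmin(Q0, Q1)
    it <- it + 1
    res <- max(abs(Jn - J))
    J <- Jn
    done <- if (is.null(iterations)) res < tol || it >= max_iterations else it >= iterations
    if (done) break
  }
  actions <- as.integer(Q1 < Q0)      # ties (Q1 == Q0) keep c = 0
  structure(
    list(actions = actions, J = J, residual = res, iterations = it,
         zeta = zeta, control_gene = problem$control_gene),
    class = "grn_policy"
  )
}

#' Intrinsically Bayesian robust (IBR) policy
#'
#' The IBR stationary policy minimizes the expected discounted cost averaged
#' over the uncertainty class; it coincides with the optimal policy of the
#' effective TPM, so it is obtained by running [value_iteration()] on the
#' ETPM.
#'
#' @param etpm effective TPM from [effective_tpm()].
#' @inheritParams value_iteration
#' @return a `grn_policy`.
#' @export
ibr_policy <- function(etpm, problem, iterations = NULL, tol = 1e-10) {
  value_iteration(etpm, problem, iterations = iterations, tol = tol)
}

#' @export
print.grn_policy <- function(x, ...) {
  cat(sprintf("Stationary control policy on %d states (control gene %d)\n",
              length(x$actions), x$control_gene))
  cat(sprintf("  intervening in %d state(s); value iteration: %d iteration(s), residual %.3g\n",
              sum(x$actions), x$iterations, x$residual))
  invisible(x)
}

#' @export
summary.grn_policy <- function(object, ...) {
  cat(sprintf("Actions: %d of %d states intervened\n",
              sum(object$actions), length(object$actions)))
  cat(sprintf("Cost-to-go J: min %.4f, mean %.4f, max %.4f\n",
              min(object$J), mean(object$J), max(object$J)))
  invisible(object)
}

#' Predict method for policies: action at given states
#'
#' @param object a `grn_policy`.
#' @param states decimal states (default: all).
#' @param ... unused.
#' @return binary action vector.
#' @export
predict.grn_policy <- function(object, states = NULL, ...) {
  if (is.null(states)) return(object$actions)
  if (any(states < 0) || any(states >= length(object$actions))) {
    stop("state out of range", call. = FALSE)
  }
  object$actions[states + 1L]
}

#' Exact policy evaluation
#'
#' Solves the linear fixed point \eqn{J = r_\mu + \zeta P_\mu J} of the policy
#' (rows of `P` taken under each state's action), unique for `zeta < 1`.
#'
#' @param P uncontrolled TPM.
#' @param policy a `grn_policy` or binary action vector by state.
#' @param problem a [control_problem()].
#' @return cost-to-go vector `J` of length `2^n`.
#' @export
policy_evaluation_exact <- function(P, policy, problem) {
  actions <- if (inherits(policy, "grn_policy")) policy$actions else as.integer(policy)
  tb <- mdp_tables(P, problem)
  S <- problem$S
  act1 <- actions == 1L
  Pmu <- tb$P0
  Pmu[act1, ] <- tb$P1[act1, , drop = FALSE]
  rmu <- ifelse(act1, tb$R1, tb$R0)
  J <- solve(diag(S) - problem$zeta * Pmu, rmu)
  as.numeric(J)
}

#' Scalar expected cost of a policy
#'
#' Uniform average of the exact cost-to-go over all initial states (all
#' initial states equally likely).
#'
#' @inheritParams policy_evaluation_exact
#' @return scalar expected discounted cost.
#' @export
expected_cost <- function(P, policy, problem) {
  mean(policy_evaluation_exact(P, policy, problem))
}

#' Exact finite-horizon discounted cost of a policy
#'
#' Deterministic counterpart of [rollout_cost()]: the expected discounted cost
#' of `horizon` transitions under the policy, computed by backward
#' accumulation over the controlled TPM and averaged uniformly over initial
#' states. Equals the `n_traj` to infinity limit of the rollout estimate.
#'
#' @inheritParams rollout_cost
#' @return scalar expected discounted cost over the horizon.
#' @export
finite_horizon_cost <- function(P, policy, problem, horizon = 6) {
  actions <- if (inherits(policy, "grn_policy")) policy$actions else as.integer(policy)
  tb <- mdp_tables(P, problem)
  act1 <- actions == 1L
  Pmu <- tb$P0
  Pmu[act1, ] <- tb$P1[act1, , drop = FALSE]
  rmu <- ifelse(act1, tb$R1, tb$R0)
  V <- numeric(problem$S)
  for (t in seq_len(horizon)) V <- rmu + problem$zeta * as.numeric(Pmu %*% V)
  mean(V)
}

#' Monte-Carlo rollout cost of a policy
#'
#' Averages the discounted cost of `n_traj` simulated trajectories of
#' `horizon` transitions (costs at `t = 0, ..., horizon - 1`), with initial
#' states drawn uniformly and transitions sampled from the controlled TPM.
#'
#' @param P uncontrolled TPM of the network the policy is applied to.
#' @param policy a `grn_policy` or binary action vector.
#' @param problem a [control_problem()].
#' @param horizon number of transitions per trajectory.
#' @param n_traj number of trajectories.
#' @param seed optional integer seed.
#' @return scalar Monte-Carlo estimate of the expected discounted cost.
#' @export
rollout_cost <- function(P, policy, problem, horizon = 6, n_traj = 10000,
                         seed = NULL) {
  stopifnot(horizon >= 1, n_traj >= 1)
  actions <- if (inherits(policy, "grn_policy")) policy$actions else as.integer(policy)
  tb <- mdp_tables(P, problem)
  S <- problem$S
  act1 <- actions == 1L
  Pmu <- tb$P0
  Pmu[act1, ] <- tb$P1[act1, , drop = FALSE]
  cum <- t(apply(Pmu, 1, cumsum))
  # per-transition cost under the policy's action at the source state
  cm0 <- cost_matrix(problem, 0)
  cm1 <- cost_matrix(problem, 1)
  cmu <- cm0
  cmu[act1, ] <- cm1[act1, , drop = FALSE]
  local_seed(seed)
  states <- sample.int(S, n_traj, replace = TRUE)   # 1-based internal
  total <- numeric(n_traj)
  disc <- 1
  for (t in seq_len(horizon)) {
    u <- stats::runif(n_traj)
    nxt <- integer(n_traj)
    for (grp in split(seq_len(n_traj), states)) {
      s <- states[grp[1]]
      nxt[grp] <- findInterval(u[grp], cum[s, ]) + 1L
    }
    nxt[nxt > S] <- S
    total <- total + disc * cmu[cbind(states, nxt)]
    disc <- disc * problem$zeta
    states <- nxt
  }
  mean(total)
}
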