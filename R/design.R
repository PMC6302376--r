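#' Experimental-design configuration
#'
#' @param method `"optimal"` (conditioned IBR policy by value iteration,
#'   scored by exact evaluation on the conditioned ETPM) or `"approximate"`
#'   (conditioned MFPT policy on the ETPM, scored by Monte-Carlo rollouts).
#' @param M Monte-Carlo samples drawn per parameter when scoring (default 20).
#' @param iterations value-iteration count for policy solves (default 4).
#' @param delta MFPT improvement threshold (default 0.3).
#' @param rollout_n trajectories per rollout estimate in the approximate
#'   method (default 1000).
#' @param horizon rollout horizon in transitions (default 6).
#' @return an object of class `design_config`.
#' @export
design_config <- function(method = c("optimal", "approximate"), M = 20,
                          iterations = 4, delta = 0.3, rollout_n = 1000,
                          horizon = 6) {
  method <- match.arg(method)
  stopifnot(M >= 1, is.null(iterations) || iterations >= 1,
            delta >= 0, rollout_n >= 1, horizon >= 1)
  structure(list(method = method, M = M, iterations = iterations,
                 delta = delta, rollout_n = rollout_n, horizon = horizon),
            class = "design_config")
}

#' Mean objective cost of uncertainty (MOCU)
#'
#' Monte-Carlo estimate of the expected excess cost of using the robust (IBR)
#' policy instead of each sampled model's own optimal policy:
#' \eqn{(1/M) \sum_m [\xi_{\theta_m}(\mu^\Theta) - \xi_{\theta_m}(\mu(\theta_m))]},
#' with \eqn{\xi} the uniform-initial-state expected discounted cost on the
#' realized TPM. Each summand is nonnegative when policies are solved to
#' convergence, so MOCU is nonnegative; it is zero iff the IBR policy is
#' optimal for every sampled model.
#'
#' @param cpms base [cpm_set()].
#' @param unc an [uncertainty_class()].
#' @param problem a [control_problem()].
#' @param M number of prior draws.
#' @param iterations value-iteration count (`NULL` = converge; convergence
#'   guarantees nonnegative summands).
#' @param seed optional integer seed.
#' @return scalar MOCU estimate.
#' @export
mocu <- function(cpms, unc, problem, M = 100, iterations = NULL, seed = NULL) {
  if (n_unknown(unc) == 0) return(0)
  robust <- ibr_policy(effective_tpm(cpms, unc), problem, iterations = iterations)
  local_seed(seed)
  total <- 0
  for (m in seq_len(M)) {
    cp <- sample_theta(cpms, unc)
    P <- tpm_from_cpms(cp)
    opt <- value_iteration(P, problem, iterations = iterations)
    total <- total + expected_cost(P, robust, problem) -
      expected_cost(P, opt, problem)
  }
  total / M
}

#' Score one candidate experiment
#'
#' The score of experiment `i` is the expected cost that remains after
#' determining parameter `i`: the Monte-Carlo average, over `M` draws
#' \eqn{\theta'_i} from the parameter's beta marginal, of the expected cost of
#' the conditioned robust policy on the conditioned ETPM. Lower is better; the
#' terms not depending on `i` in the expected-remaining-MOCU objective are
#' dropped, so ranking these scores ranks experiments.
#'
#' @param cpms base [cpm_set()].
#' @param unc an [uncertainty_class()].
#' @param problem a [control_problem()].
#' @param index parameter (row of `unc`) whose experiment is scored; must be
#'   unrevealed.
#' @param cfg a [design_config()].
#' @param seed optional integer seed.
#' @return scalar score (expected remaining cost).
#' @export
score_experiment <- function(cpms, unc, problem, index, cfg = design_config(),
                             seed = NULL) {
  if (index < 1 || index > nrow(unc)) stop("parameter index out of range", call. = FALSE)
  if (!is.na(unc$value[index])) stop("parameter already revealed", call. = FALSE)
  local_seed(seed)
  draws <- stats::rbeta(cfg$M, unc$alpha[index], unc$beta[index])
  # Across the M draws only the scored gene's CPM row changes, so the other
  # genes' contribution to the conditioned ETPM is precomputed once.
  n <- cpms$n
  g <- unc$gene[index]
  eff <- set_cpm_entries(cpms, unc, posterior_mean(unc))
  base <- matrix(1, 2^n, 2^n)
  for (kk in setdiff(seq_len(n), g)) {
    base <- base * gene_factor(eff$matrices[[kk]], eff$regulators[[kk]], kk, n)
  }
  Cg <- eff$matrices[[g]]
  total <- 0
  for (m in seq_len(cfg$M)) {
    Cg[unc$context[index] + 1L, ] <- c(draws[m], 1 - draws[m])
    etpm <- base * gene_factor(Cg, eff$regulators[[g]], g, n)
    if (cfg$method == "optimal") {
      pol <- ibr_policy(etpm, problem, iterations = cfg$iterations)
      total <- total + expected_cost(etpm, pol, problem)
    } else {
      pol <- approx_ibr_policy(etpm, problem, delta = cfg$delta)
      total <- total + rollout_cost(etpm, pol, problem, horizon = cfg$horizon,
                                    n_traj = cfg$rollout_n)
    }
  }
  total / cfg$M
}

#' Select the best experiment
#'
#' Scores every unrevealed parameter with [score_experiment()] and returns the
#' ascending ranking; the experiment with the smallest expected remaining cost
#' is the optimal (first) experiment. Ties break to the lowest parameter
#' index.
#'
#' @inheritParams score_experiment
#' @return an object of class `design_report`: list with `scores` (named by
#'   parameter row), `ranking` (parameter rows, best first), `selected`.
#' @export
select_experiment <- function(cpms, unc, problem, cfg = design_config(),
                              seed = NULL) {
  open <- which(is.na(unc$value))
  if (length(open) == 0) stop("no unrevealed parameters to design for", call. = FALSE)
  scores <- vapply(seq_along(open), function(q) {
    score_experiment(cpms, unc, problem, open[q], cfg,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, q))
  }, numeric(1))
  ord <- order(scores, open)          # ties -> lowest parameter index
  structure(
    list(scores = stats::setNames(scores, open), ranking = open[ord],
         selected = open[ord][1], method = cfg$method),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("Experiment selection (%s method)\n", x$method))
  cat("  scores (expected remaining cost):\n")
  for (q in seq_along(x$scores)) {
    cat(sprintf("    parameter %s: %.4f\n", names(x$scores)[q], x$scores[q]))
  }
  cat(sprintf("  ranking: %s\n", paste(x$ranking, collapse = " > ")))
  cat(sprintf("  selected experiment: parameter %d\n", x$selected))
  invisible(x)
}

#' Cost of determining one parameter
#'
#' Implements the evaluation protocol: reveal the parameter's true value, find
#' the IBR policy of the conditioned class by value iteration on the
#' conditioned ETPM (always value iteration, also when the design used the
#' MFPT approximation), apply that policy to the underlying true network, and
#' average the discounted costs of `n_traj` rollouts of `horizon` transitions
#' with uniformly drawn initial states.
#'
#' @param true_tpm TPM of the underlying true network.
#' @param cpms base [cpm_set()].
#' @param unc an [uncertainty_class()].
#' @param problem a [control_problem()].
#' @param index parameter to determine (`NULL`: evaluate the current class
#'   without revealing anything).
#' @param true_value the parameter's true conditional probability.
#' @param iterations value-iteration count (default 4).
#' @param n_traj rollout count (default 10000).
#' @param horizon rollout horizon (default 6).
#' @param seed optional integer seed for the rollouts.
#' @param exact evaluate the horizon cost deterministically by backward
#'   accumulation ([finite_horizon_cost()], the `n_traj` to infinity limit)
#'   instead of by Monte-Carlo rollouts.
#' @return scalar average discounted cost `J(theta_i)`.
#' @export
evaluate_determination <- function(true_tpm, cpms, unc, problem, index = NULL,
                                   true_value = NULL, iterations = 4,
                                   n_traj = 10000, horizon = 6, seed = NULL,
                                   exact = FALSE) {
  if (!is.null(index)) unc <- condition_on(unc, index, true_value)
  pol <- ibr_policy(effective_tpm(cpms, unc), problem, iterations = iterations)
  if (exact) {
    finite_horizon_cost(true_tpm, pol, problem, horizon = horizon)
  } else {
    rollout_cost(true_tpm, pol, problem, horizon = horizon, n_traj = n_traj,
                 seed = seed)
  }
}

#' Classify the outcome of an experiment comparison
#'
#' @param J_a,J_b average costs after the compared experiments.
#' @param tol classification threshold (default 0.002); success when
#'   `J_a - J_b < -tol`, failure when `> tol`, tie otherwise (the exact
#'   boundary counts as a tie).
#' @return `"success"`, `"failure"`, or `"tie"`.
#' @export
compare_outcomes <- function(J_a, J_b, tol = 0.002) {
  stopifnot(tol > 0)
  d <- J_a - J_b
  eps <- 1e-12          # exact boundary (|d| == tol) classifies as a tie
  if (d < -tol - eps) "success" else if (d > tol + eps) "failure" else "tie"
}

#' Sequential experimental design
#'
#' Runs the full design loop: at each step the selection policy picks an
#' experiment (MOCU-based scoring, or uniform random for the baseline), the
#' parameter's true value is revealed and conditioned on, and the cost of the
#' resulting IBR policy on the true network is recorded. Step 0 is the cost
#' before any experiment; after `budget = T` steps the model is fully
#' identified and the policy is optimal for the true network. Evaluation
#' rollout seeds are derived from `seed` and the step number only, so
#' different selection policies share identical endpoint evaluations.
#'
#' @param cpms base [cpm_set()].
#' @param unc initial [uncertainty_class()].
#' @param problem a [control_problem()].
#' @param true_values numeric vector of true conditional probabilities, one
#'   per row of `unc`.
#' @param cfg a [design_config()]; ignored by the random policy.
#' @param budget number of experiments to perform (at most `n_unknown(unc)`).
#' @param policy `"optimal"`, `"approximate"`, or `"random"`.
#' @param eval_n,eval_horizon,eval_iterations evaluation protocol (defaults
#'   10000 rollouts, horizon 6, 4 value-iteration steps).
#' @param eval_exact use the deterministic finite-horizon evaluation instead
#'   of rollouts (see [evaluate_determination()]).
#' @param seed integer seed governing selection and evaluation streams.
#' @return an object of class `design_report` with `steps`: a data frame of
#'   `step`, `chosen` (parameter row, `NA` at step 0) and `cost`.
#' @export
sequential_design <- function(cpms, unc, problem, true_values,
                              cfg = design_config(), budget = NULL,
                              policy = c("optimal", "approximate", "random"),
                              eval_n = 10000, eval_horizon = 6,
                              eval_iterations = 4, eval_exact = FALSE,
                              seed = NULL) {
  policy <- match.arg(policy)
  stopifnot(length(true_values) == nrow(unc))
  Tn <- n_unknown(unc)
  if (is.null(budget)) budget <- Tn
  if (budget > Tn) stop("budget exceeds the number of unrevealed parameters", call. = FALSE)
  if (policy != "random") cfg$method <- if (policy == "optimal") "optimal" else "approximate"
  true_tpm <- tpm_from_cpms(set_cpm_entries(cpms, unc, true_values))
  steps <- data.frame(step = 0:budget, chosen = NA_integer_, cost = NA_real_)
  steps$cost[1] <- evaluate_determination(
    true_tpm, cpms, unc, problem, iterations = eval_iterations,
    n_traj = eval_n, horizon = eval_horizon, exact = eval_exact,
    seed = if (is.null(seed)) NULL else derive_seed(seed, 0L, 9L))
  if (budget > 0) for (b in seq_len(budget)) {
    open <- which(is.na(unc$value))
    chosen <- if (policy == "random") {
      local_seed(if (is.null(seed)) NULL else derive_seed(seed, b, 7L))
      open[sample.int(length(open), 1)]
    } else {
      select_experiment(cpms, unc, problem, cfg,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, b, 3L))$selected
    }
    unc <- condition_on(unc, chosen, true_values[chosen])
    steps$chosen[b + 1] <- chosen
    steps$cost[b + 1] <- evaluate_determination(
      true_tpm, cpms, unc, problem, iterations = eval_iterations,
      n_traj = eval_n, horizon = eval_horizon, exact = eval_exact,
      seed = if (is.null(seed)) NULL else derive_seed(seed, b, 9L))
  }
  structure(list(steps = steps, policy = policy, budget = budget),
            class = c("sequential_design", "design_report"))
}

#' @export
print.sequential_design <- function(x, ...) {
  cat(sprintf("Sequential design (%s policy), %d experiment(s)\n",
              x$policy, x$budget))
  print(x$steps, row.names = FALSE)
  invisible(x)
}
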