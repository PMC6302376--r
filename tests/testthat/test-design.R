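test_that("MOCU is nonnegative and vanishes without uncertainty", {
  cpms <- two_gene_cpms(seed = 11)
  pr <- two_gene_problem()
  empty <- uncertainty_class(integer(0), integer(0))
  expect_equal(mocu(cpms, empty, pr, M = 5, seed = 1), 0)
  unc <- uncertainty_class(gene = c(1, 2), context = c(1, 2))
  # each summand is >= 0 exactly when policies are solved to convergence
  for (s in 1:5) expect_gte(mocu(cpms, unc, pr, M = 30, seed = s), 0)
  # 6-gene instance as well
  net <- random_bnp(seed = 61)
  P <- bnp_tpm(net)
  cp6 <- cpms_from_tpm(P, net$regulators)
  unc6 <- uncertainty_class(gene = c(2, 5), context = c(0, 3))
  expect_gte(mocu(cp6, unc6, control_problem(6, 6, 0:15), M = 20, seed = 9), 0)
})

test_that("Monte-Carlo MOCU agrees with fine-grid quadrature", {
  cpms <- two_gene_cpms(seed = 13)
  pr <- two_gene_problem()
  unc <- uncertainty_class(gene = 1, context = 2, alpha = 2, beta = 3)
  robust <- ibr_policy(effective_tpm(cpms, unc), pr, tol = 1e-12)
  ocu_at <- function(th) {
    P <- tpm_from_cpms(mocudesign:::set_cpm_entries(cpms, unc, th))
    opt <- value_iteration(P, pr, tol = 1e-12)
    expected_cost(P, robust, pr) - expected_cost(P, opt, pr)
  }
  quad <- beta_quadrature(ocu_at, 2, 3, n_grid = 1001)
  draws <- vapply(1:20, function(r) mocu(cpms, unc, pr, M = 500, seed = 100 + r),
                  numeric(1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - quad), 3 * se + 1e-8)
})

test_that("experiment scores match quadrature and never exceed the prior cost", {
  cpms <- two_gene_cpms(seed = 17)
  pr <- two_gene_problem()
  unc <- uncertainty_class(gene = c(1, 2), context = c(0, 1),
                           alpha = c(1, 2), beta = c(1, 2))
  cfg <- design_config("optimal", M = 400, iterations = NULL)
  # quadrature oracle for the score of parameter 1: conditioning leaves
  # parameter 2 open; the conditioned IBR policy is evaluated on the
  # conditioned ETPM
  remaining_cost <- function(th, index) {
    u <- condition_on(unc, index, th)
    et <- effective_tpm(cpms, u)
    pol <- ibr_policy(et, pr, tol = 1e-12)
    expected_cost(et, pol, pr)
  }
  for (index in 1:2) {
    quad <- beta_quadrature(function(th) remaining_cost(th, index),
                            unc$alpha[index], unc$beta[index], n_grid = 1001)
    draws <- vapply(1:10, function(r) {
      score_experiment(cpms, unc, pr, index, cfg, seed = 200 + r)
    }, numeric(1))
    se <- stats::sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - quad), 3 * se + 1e-8)
    # information never hurts: conditioning does not increase the expected
    # cost of the robust policy (quadrature-exact on this instance)
    et0 <- effective_tpm(cpms, unc)
    prior_cost <- expected_cost(et0, ibr_policy(et0, pr, tol = 1e-12), pr)
    expect_lte(quad, prior_cost + 1e-9)
  }
})

test_that("selection ranks scores ascending and is reproducible", {
  net <- random_bnp(seed = 71)
  P <- bnp_tpm(net)
  cpms <- cpms_from_tpm(P, net$regulators)
  pr <- control_problem(6, 6, 0:15)
  unc <- uncertainty_class(gene = c(1, 3, 5), context = c(0, 1, 2))
  cfg <- design_config("optimal", M = 10)
  rep1 <- select_experiment(cpms, unc, pr, cfg, seed = 5)
  rep2 <- select_experiment(cpms, unc, pr, cfg, seed = 5)
  expect_identical(rep1, rep2)                       # byte-for-byte under seed
  expect_equal(rep1$selected, rep1$ranking[1])
  expect_equal(rep1$ranking, as.integer(names(sort(rep1$scores))))
  # T = 1: the only parameter is selected
  u1 <- uncertainty_class(gene = 2, context = 3)
  expect_equal(select_experiment(cpms, u1, pr, cfg, seed = 1)$selected, 1)
  # revealed parameters are not scored
  u2 <- condition_on(unc, 2, 0.4)
  expect_false(2 %in% select_experiment(cpms, u2, pr, cfg, seed = 1)$ranking)
  expect_error(select_experiment(cpms, condition_on(u1, 1, 0.3), pr, cfg), "no unrevealed")
  # approximate-method selection is also seed-reproducible
  cfga <- design_config("approximate", M = 5, rollout_n = 200)
  expect_identical(select_experiment(cpms, unc, pr, cfga, seed = 3)$scores,
                   select_experiment(cpms, unc, pr, cfga, seed = 3)$scores)
})

test_that("an experiment with no bearing on the cost is never preferred", {
  # Cost depends only on X1 (U = states with X1 = 0). Gene 1 reads X2; while
  # gene 1's CPM rows are at the prior mean 0.5, X1 is a fair coin whatever
  # the policy does, so determining gene 2's CPM cannot change the cost.
  # Determining gene 1's row 0 makes X1 depend on X2 and lets the control
  # gene (X2) steer away from U, so its expected remaining cost is lower.
  regs <- list(2L, 2L)
  mats <- list(
    cbind(c(0.5, 0.5), c(0.5, 0.5)),   # gene 1 | X2 context (row 0 blinded)
    cbind(c(0.7, 0.4), c(0.3, 0.6))    # gene 2 | its own value (row 1 blinded)
  )
  cpms <- cpm_set(mats, regs)
  pr <- two_gene_problem()
  # parameter 1: gene 2 at context X2 = 1 (no influence on the cost);
  # parameter 2: gene 1 at context X2 = 0 (directly steers the phenotype bit)
  unc <- uncertainty_class(gene = c(2, 1), context = c(1, 0))
  score <- function(index) {
    beta_quadrature(function(th) {
      u <- condition_on(unc, index, th)
      et <- effective_tpm(cpms, u)
      expected_cost(et, ibr_policy(et, pr, tol = 1e-12), pr)
    }, 1, 1, n_grid = 501)
  }
  expect_lt(score(2), score(1))
})

test_that("outcome comparison classifies with the 0.002 threshold", {
  expect_equal(compare_outcomes(1.0, 1.003), "success")
  expect_equal(compare_outcomes(1.003, 1.0), "failure")
  expect_equal(compare_outcomes(1.0005, 1.0), "tie")
  expect_equal(compare_outcomes(1.002, 1.0), "tie")   # exact boundary -> tie
  expect_equal(compare_outcomes(1.0, 1.0025), "success")
})

test_that("determination evaluation follows the reveal-solve-rollout protocol", {
  # zero cost table -> 0
  cpms <- two_gene_cpms(seed = 19)
  unc <- uncertainty_class(gene = 1, context = 0)
  tt <- tpm_from_cpms(mocudesign:::set_cpm_entries(cpms, unc, 0.3))
  pr0 <- control_problem(2, 2, undesirable = 0, cost = function(i, j, c) 0)
  expect_equal(evaluate_determination(tt, cpms, unc, pr0, index = 1,
                                      true_value = 0.3, n_traj = 50, seed = 1), 0)
  # absorbing-in-U network: geometric sum 5(1-0.2^6)/0.8
  cp_abs <- cpm_set(list(cbind(c(1, 1), c(0, 0))), list(1L))
  u_abs <- uncertainty_class(integer(0), integer(0))
  t_abs <- tpm_from_cpms(cp_abs)                     # both states -> state 0
  pr_abs <- control_problem(1, 1, undesirable = 0,
                            cost = function(i, j, c) 5 * (j == 0))
  expect_equal(evaluate_determination(t_abs, cp_abs, u_abs, pr_abs,
                                      n_traj = 20, seed = 2),
               5 * (1 - 0.2^6) / 0.8, tolerance = 1e-12)
  # finite-horizon backward-accumulation oracle for the rollout average
  net <- random_bnp(n = 3, k = 2, seed = 23)
  P <- bnp_tpm(net)
  cp3 <- cpms_from_tpm(P, net$regulators)
  un3 <- uncertainty_class(gene = 2, context = 1)
  pr3 <- control_problem(3, 3, undesirable = 0:1)
  tt3 <- tpm_from_cpms(mocudesign:::set_cpm_entries(cp3, un3, 0.7))
  pol <- ibr_policy(effective_tpm(cp3, condition_on(un3, 1, 0.7)), pr3,
                    iterations = 4)
  act <- pol$actions == 1
  Pmu <- tt3
  Pmu[act, ] <- controlled_tpm(tt3, 3, 1)[act, ]
  cm <- matrix(5 * ((0:7) %in% 0:1), 8, 8, byrow = TRUE) +
    matrix(as.numeric(act), 8, 8)
  V <- numeric(8)
  for (t in 5:0) V <- rowSums(Pmu * cm) + 0.2 * as.numeric(Pmu %*% V) * (t < 5)
  exact <- mean(V)
  draws <- vapply(1:10, function(r) {
    evaluate_determination(tt3, cp3, un3, pr3, index = 1, true_value = 0.7,
                           n_traj = 4000, seed = 400 + r)
  }, numeric(1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - exact), 3 * se + 1e-8)
})

test_that("sequential design identifies the model within budget", {
  net <- random_bnp(seed = 83)
  P <- bnp_tpm(net)
  cpms <- cpms_from_tpm(P, net$regulators)
  pr <- control_problem(6, 6, 0:15)
  unc <- uncertainty_class(gene = c(1, 2, 4), context = c(0, 2, 3))
  set.seed(42)
  phi <- stats::rbeta(3, 1, 1)
  cfg <- design_config("optimal", M = 5)
  run <- sequential_design(cpms, unc, pr, phi, cfg, budget = 3,
                           policy = "optimal", eval_n = 500, seed = 7)
  expect_equal(nrow(run$steps), 4)
  expect_setequal(run$steps$chosen[-1], 1:3)          # all parameters revealed
  # budget 0: only the initial cost
  run0 <- sequential_design(cpms, unc, pr, phi, cfg, budget = 0,
                            policy = "optimal", eval_n = 500, seed = 7)
  expect_equal(nrow(run0$steps), 1)
  expect_equal(run0$steps$cost[1], run$steps$cost[1])  # shared evaluation seed
  expect_error(sequential_design(cpms, unc, pr, phi, cfg, budget = 4,
                                 policy = "optimal", seed = 1), "budget")
  # endpoints equal across selection policies (shared evaluation streams)
  run_r <- sequential_design(cpms, unc, pr, phi, cfg, budget = 3,
                             policy = "random", eval_n = 500, seed = 7)
  expect_equal(run_r$steps$cost[1], run$steps$cost[1])
  expect_equal(run_r$steps$cost[4], run$steps$cost[4])
  # full identification: final policy equals the true network's optimal policy
  unc_full <- unc
  for (q in 1:3) unc_full <- condition_on(unc_full, q, phi[q])
  tt <- tpm_from_cpms(mocudesign:::set_cpm_entries(cpms, unc, phi))
  expect_equal(effective_tpm(cpms, unc_full), tt, tolerance = 1e-12)
})

test_that("benchmark tables are internally consistent and deterministic", {
  b <- run_benchmark(n_networks = 2, n_truth = 2, eval_n = 300, M = 4,
                     rollout_n = 100, seed = 3)
  expect_equal(nrow(b$table1), 5)
  expect_equal(b$table2$policy, c("random", "approximate", "optimal"))
  expect_equal(b$table2$mean_cost[3], b$table1$optimal[1])
  expect_equal(b$table2$mean_cost[2], b$table1$approximate[1])
  rowsum3 <- b$table3$success + b$table3$failure + b$table3$tie
  expect_equal(rowsum3, rep(100, nrow(b$table3)), tolerance = 1e-9)
  b2 <- run_benchmark(n_networks = 2, n_truth = 2, eval_n = 300, M = 4,
                      rollout_n = 100, seed = 3)
  expect_identical(b$raw, b2$raw)                     # full-pipeline determinism
  # with a single unknown all selection policies coincide
  b1 <- run_benchmark(n_networks = 1, n_truth = 2, n_unknown = 1, eval_n = 200,
                      M = 3, rollout_n = 100, seed = 5)
  expect_equal(b1$table2$mean_cost[1], b1$table2$mean_cost[2])
  expect_equal(b1$table2$mean_cost[2], b1$table2$mean_cost[3])
})
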