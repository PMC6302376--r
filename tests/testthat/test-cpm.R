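test_that("TPM from CPMs follows the gene-wise factorization", {
  cpms <- two_gene_cpms()
  P <- tpm_from_cpms(cpms)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  # hand factorization for one entry: P_{i=1, j=2} with both genes reading (X1,X2)
  # source 1 = (0,1) -> context 1 for both; target 2 = (1,0): gene1 = 1, gene2 = 0
  expect_equal(P[2, 3],
               cpms$matrices[[1]][2, 2] * cpms$matrices[[2]][2, 1],
               tolerance = 1e-14)
  # degenerate CPMs: every gene deterministically 1 -> single mass on all-ones
  det <- cpm_set(list(matrix(c(0, 1), 4, 2, byrow = TRUE),
                      matrix(c(0, 1), 4, 2, byrow = TRUE)),
                 list(c(1L, 2L), c(1L, 2L)))
  Pd <- tpm_from_cpms(det)
  expect_equal(Pd[, 4], rep(1, 4))
  expect_error(cpm_set(list(matrix(0.5, 2, 2)), list(c(1L, 2L))), "must be")
})

test_that("CPM extraction inverts the factorization and BNp construction", {
  # factorized TPM: exact recovery
  cpms <- two_gene_cpms(seed = 7)
  P <- tpm_from_cpms(cpms)
  rec <- cpms_from_tpm(P, cpms$regulators)
  for (i in 1:2) {
    expect_equal(rec$matrices[[i]], cpms$matrices[[i]], tolerance = 1e-10)
  }
  # full round trip on a BNp: bnp_tpm -> cpms_from_tpm -> tpm_from_cpms
  net <- random_bnp(seed = 31)
  P6 <- bnp_tpm(net)
  P6b <- tpm_from_cpms(cpms_from_tpm(P6, net$regulators))
  expect_lt(max(abs(P6 - P6b)), 1e-10)
  # rows always sum to one by construction (the two sums partition each row)
  arb <- random_stochastic(8, seed = 5)
  cp <- cpms_from_tpm(arb, list(1L, c(1L, 2L), c(2L, 3L)))
  for (M in cp$matrices) expect_equal(rowSums(M), rep(1, nrow(M)), tolerance = 1e-12)
})

test_that("extraction averages the row masses over matching contexts", {
  # 2-gene chain, gene 1 regulated by gene 2 only: contexts pair up rows
  P <- random_stochastic(4, seed = 9)
  cp <- cpms_from_tpm(P, list(2L, c(1L, 2L)))
  # context X2 = 0 matches source states (0,0) and (1,0) = rows 1, 3;
  # mass on targets with X1 = 0 is columns 1:2
  expected <- mean(c(sum(P[1, 1:2]), sum(P[3, 1:2])))
  expect_equal(cp$matrices[[1]][1, 1], expected, tolerance = 1e-12)
  # steady-state weighting uses pi instead of the plain mean
  cpw <- cpms_from_tpm(P, list(2L, c(1L, 2L)), weights = "steady_state")
  pi <- steady_state(P)
  expected_w <- (pi[1] * sum(P[1, 1:2]) + pi[3] * sum(P[3, 1:2])) / (pi[1] + pi[3])
  expect_equal(cpw$matrices[[1]][1, 1], expected_w, tolerance = 1e-12)
})

test_that("posterior updating counts context-matched transitions", {
  regs <- list(c(1L, 2L), c(1L, 2L))
  unc <- uncertainty_class(gene = 1, context = 1)   # X1's context (X1,X2) = (0,1)
  # empty trajectory: unchanged
  expect_equal(update_posteriors(unc, integer(1), regs, 2)[, c("alpha", "beta")],
               unc[, c("alpha", "beta")])
  # trajectory visiting context 1 twice: outcomes X1 = 0 then X1 = 1
  # states: 1 = (0,1) -> 0 = (0,0): X1(l+1) = 0 counts alpha
  #         1 = (0,1) -> 2 = (1,0): X1(l+1) = 1 counts beta
  traj <- c(1, 0, 1, 2, 3)
  up <- update_posteriors(unc, traj, regs, 2)
  expect_equal(up$alpha, 2)
  expect_equal(up$beta, 2)
  expect_equal(posterior_mean(up), 0.5)
  # total added counts = number of transitions matching the context
  src <- traj[-length(traj)]
  matches <- sum(src == 1)
  expect_equal((up$alpha - 1) + (up$beta - 1), matches)
  expect_error(update_posteriors(unc, c(0, 4), regs, 2), "out of range")
})

test_that("updating is additive over concatenated trajectories", {
  net <- random_bnp(n = 3, k = 2, p = 0.1, seed = 77)
  P <- bnp_tpm(net)
  unc <- uncertainty_class(gene = c(1, 2, 3), context = c(0, 1, 3))
  traj <- simulate_trajectory(P, 400, seed = 13)
  whole <- update_posteriors(unc, traj, net$regulators, 3)
  first <- update_posteriors(unc, traj[1:201], net$regulators, 3)
  second <- update_posteriors(first, traj[201:401], net$regulators, 3)
  expect_equal(whole$alpha, second$alpha)
  expect_equal(whole$beta, second$beta)
})

test_that("posterior concentrates on the truth as data grow", {
  net <- random_bnp(n = 3, k = 2, p = 0.1, seed = 55)
  P <- bnp_tpm(net)
  cpms <- cpms_from_tpm(P, net$regulators)
  unc <- uncertainty_class(gene = 2, context = 1)
  truth <- cpms$matrices[[2]][2, 1]
  errs <- vapply(c(1e2, 1e4), function(L) {
    traj <- simulate_trajectory(P, L, seed = 101)
    abs(posterior_mean(update_posteriors(unc, traj, net$regulators, 3)) - truth)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.05)
})

test_that("beta moments of posterior mean and samples agree", {
  expect_equal(posterior_mean(uncertainty_class(1, 0, 1, 1)), 0.5)
  expect_equal(posterior_mean(uncertainty_class(1, 0, 2, 2)), 0.5)
  expect_equal(posterior_mean(uncertainty_class(1, 0, 3, 2)), 0.6)
  cpms <- two_gene_cpms()
  unc <- uncertainty_class(gene = 1, context = 2, alpha = 3, beta = 2)
  draws <- vapply(1:10000, function(r) {
    sample_theta(cpms, unc, seed = 5000 + r)$matrices[[1]][3, 1]
  }, numeric(1))
  se <- sqrt(0.6 * 0.4 / (3 + 2 + 1)) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.6), 3 * se)
})

test_that("effective TPM is the prior mean of sampled TPMs", {
  cpms <- two_gene_cpms(seed = 3)
  unc <- uncertainty_class(gene = c(1, 2), context = c(0, 3),
                           alpha = c(2, 1), beta = c(5, 1))
  et <- effective_tpm(cpms, unc)
  expect_equal(rowSums(et), rep(1, 4), tolerance = 1e-12)
  # invariant to parameter order in the class
  unc_rev <- uncertainty_class(gene = c(2, 1), context = c(3, 0),
                               alpha = c(1, 2), beta = c(1, 5))
  expect_equal(effective_tpm(cpms, unc_rev), et, tolerance = 1e-14)
  # empty class: plain factorized TPM
  empty <- uncertainty_class(integer(0), integer(0))
  expect_equal(effective_tpm(cpms, empty), tpm_from_cpms(cpms))
  # Beta(1,1) unknown: entries computed with 0.5 in that context
  u11 <- uncertainty_class(gene = 1, context = 0)
  cp_half <- cpms
  cp_half$matrices[[1]][1, ] <- c(0.5, 0.5)
  expect_equal(effective_tpm(cpms, u11), tpm_from_cpms(cp_half), tolerance = 1e-14)
  # Monte-Carlo oracle: mean of sampled TPMs within 3 s.e. entrywise
  nmc <- 20000
  acc <- matrix(0, 4, 4)
  acc2 <- matrix(0, 4, 4)
  set.seed(17)
  for (m in seq_len(nmc)) {
    Pm <- tpm_from_cpms(sample_theta(cpms, unc))
    acc <- acc + Pm
    acc2 <- acc2 + Pm^2
  }
  mc_mean <- acc / nmc
  mc_se <- sqrt(pmax(acc2 / nmc - mc_mean^2, 0) / nmc)
  expect_true(all(abs(et - mc_mean) <= 3 * mc_se + 1e-9))
})

test_that("conditioning reveals parameters one at a time", {
  cpms <- two_gene_cpms()
  unc <- uncertainty_class(gene = c(1, 2), context = c(0, 3))
  expect_equal(n_unknown(unc), 2)
  u1 <- condition_on(unc, 1, 0.25)
  expect_equal(n_unknown(u1), 1)
  u2 <- condition_on(u1, 2, 0.75)
  expect_equal(n_unknown(u2), 0)
  # all parameters conditioned: ETPM equals the realized-CPM TPM
  realized <- mocudesign:::set_cpm_entries(cpms, unc, c(0.25, 0.75))
  expect_equal(effective_tpm(cpms, u2), tpm_from_cpms(realized), tolerance = 1e-14)
  expect_error(condition_on(unc, 3, 0.5), "out of range")
  expect_error(uncertainty_class(1, 0, alpha = 0), "positive")
})
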