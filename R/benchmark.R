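#' Synthetic-network benchmark of the design methods
#'
#' Reproduces the synthetic study protocol: generate random Boolean networks
#' with perturbation, extract their CPMs, blind a random subset of conditional
#' probabilities, draw assumed true values from the beta priors, rank the
#' candidate experiments with both the optimal and the MFPT-approximate design
#' method, and measure the average cost `J` obtained after performing each
#' ranked experiment (conditioned IBR policy applied to the true network,
#' discounted rollouts). A uniform-random selection policy provides the
#' baseline. The cost of determining a given parameter is computed once per
#' (network, truth set) and shared by all selection policies, which pairs the
#' policy comparisons exactly.
#'
#' @param n_networks number of random networks.
#' @param n_truth number of assumed-true-value draws per network.
#' @param n_unknown number of blinded conditional probabilities `T` (default 5).
#' @param L length of the observed state trajectory used to update priors
#'   before design (default 0 = no initial data).
#' @param n_genes,k,p random-network parameters (defaults 6 genes, 2
#'   regulators, perturbation 0.01).
#' @param control_gene control gene (default: the last gene).
#' @param undesirable undesirable states (default: `X1 = 0, X2 = 0`).
#' @param zeta discount factor (default 0.2).
#' @param iterations value-iteration count (default 4).
#' @param delta MFPT threshold (default 0.3).
#' @param M Monte-Carlo draws per parameter in scoring (default 20).
#' @param rollout_n rollout count for approximate-method scoring (default 1000).
#' @param eval_n,horizon evaluation protocol (defaults 10000 rollouts,
#'   horizon 6).
#' @param seed integer seed; every stage derives its own sub-stream.
#' @return an object of class `design_benchmark`: list with `table1` (mean
#'   cost by method and rank), `table2` (mean cost by selection policy),
#'   `table3` (success/failure/tie percentages for the top experiment vs each
#'   lower rank), and `raw` (per network x truth set costs and rankings).
#' @export
run_benchmark <- function(n_networks = 100, n_truth = 100, n_unknown = 5,
                          L = 0, n_genes = 6, k = 2, p = 0.01,
                          control_gene = n_genes,
                          undesirable = states_with_bits(n_genes, c(1, 2), c(0, 0)),
                          zeta = 0.2, iterations = 4, delta = 0.3, M = 20,
                          rollout_n = 1000, eval_n = 10000, horizon = 6,
                          seed = 1) {
  problem <- control_problem(n_genes, control_gene, undesirable, zeta = zeta)
  cfg_opt <- design_config("optimal", M = M, iterations = iterations,
                           delta = delta, rollout_n = rollout_n, horizon = horizon)
  cfg_apx <- design_config("approximate", M = M, iterations = iterations,
                           delta = delta, rollout_n = rollout_n, horizon = horizon)
  rows <- vector("list", n_networks * n_truth)
  r <- 0
  for (w in seq_len(n_networks)) {
    net <- random_bnp(n = n_genes, k = k, p = p, seed = derive_seed(seed, w, 1L))
    P <- bnp_tpm(net)
    cpms <- cpms_from_tpm(P, net$regulators)
    # blind n_unknown distinct (gene, context) conditional probabilities
    local_seed(derive_seed(seed, w, 2L))
    pick <- sample.int(n_genes * 2^k, n_unknown)
    unc0 <- uncertainty_class(gene = (pick - 1L) %/% 2^k + 1L,
                              context = (pick - 1L) %% 2^k)
    rank_opt0 <- rank_apx0 <- NULL
    for (v in seq_len(n_truth)) {
      local_seed(derive_seed(seed, w, v, 3L))
      phi <- stats::rbeta(n_unknown, unc0$alpha, unc0$beta)
      true_tpm <- tpm_from_cpms(set_cpm_entries(cpms, unc0, phi))
      unc <- unc0
      if (L > 0) {
        traj <- simulate_trajectory(true_tpm, L, seed = derive_seed(seed, w, v, 4L))
        unc <- update_posteriors(unc, traj, cpms$regulators, n_genes)
      }
      if (L > 0 || is.null(rank_opt0)) {
        rank_opt0 <- select_experiment(cpms, unc, problem, cfg_opt,
                                       seed = derive_seed(seed, w, v, 5L))$ranking
        rank_apx0 <- select_experiment(cpms, unc, problem, cfg_apx,
                                       seed = derive_seed(seed, w, v, 6L))$ranking
      }
      J <- vapply(seq_len(n_unknown), function(i) {
        evaluate_determination(true_tpm, cpms, unc, problem, index = i,
                               true_value = phi[i], iterations = iterations,
                               n_traj = eval_n, horizon = horizon,
                               seed = derive_seed(seed, w, v, 9L, i))
      }, numeric(1))
      local_seed(derive_seed(seed, w, v, 8L))
      rnd_idx <- sample.int(n_unknown, 1)
      r <- r + 1
      rows[[r]] <- data.frame(
        network = w, truth = v,
        rank = seq_len(n_unknown),
        J_opt_rank = J[rank_opt0], J_apx_rank = J[rank_apx0],
        J_rnd = J[rnd_idx])
    }
  }
  raw <- do.call(rbind, rows)
  table1 <- data.frame(
    rank = seq_len(n_unknown),
    optimal = vapply(seq_len(n_unknown),
                     function(rk) mean(raw$J_opt_rank[raw$rank == rk]), numeric(1)),
    approximate = vapply(seq_len(n_unknown),
                         function(rk) mean(raw$J_apx_rank[raw$rank == rk]), numeric(1)))
  table2 <- data.frame(
    policy = c("random", "approximate", "optimal"),
    mean_cost = c(mean(raw$J_rnd[raw$rank == 1]),
                  table1$approximate[1], table1$optimal[1]))
  table3 <- benchmark_outcomes(raw, n_unknown)
  structure(list(table1 = table1, table2 = table2, table3 = table3, raw = raw,
                 settings = list(n_networks = n_networks, n_truth = n_truth,
                                 n_unknown = n_unknown, L = L, seed = seed)),
            class = "design_benchmark")
}

# Success/failure/tie percentages of the top-ranked vs each lower-ranked
# experiment, per method.
benchmark_outcomes <- function(raw, n_unknown, tol = 0.002) {
  out <- list()
  for (method in c("optimal", "approximate")) {
    col <- if (method == "optimal") "J_opt_rank" else "J_apx_rank"
    top <- raw[[col]][raw$rank == 1]
    for (rk in 2:n_unknown) {
      diff <- top - raw[[col]][raw$rank == rk]
      out[[length(out) + 1]] <- data.frame(
        method = method, comparison = sprintf("1' vs %d'", rk),
        success = 100 * mean(diff < -tol),
        failure = 100 * mean(diff > tol),
        tie = 100 * mean(abs(diff) <= tol))
    }
  }
  do.call(rbind, out)
}

#' @export
print.design_benchmark <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Design benchmark: %d networks x %d truth sets, T = %d, L = %d\n",
              s$n_networks, s$n_truth, s$n_unknown, s$L))
  cat("\nMean cost after each ranked experiment:\n")
  print(x$table1, row.names = FALSE, digits = 6)
  cat("\nMean cost by selection policy:\n")
  print(x$table2, row.names = FALSE, digits = 6)
  cat("\nTop experiment vs lower ranks (percent):\n")
  print(x$table3, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sequential-design cost curves over random networks
#'
#' Replicates the sequential-experiment protocol: for each random network and
#' each assumed-true-value draw, run [sequential_design()] to exhaustion under
#' each selection policy and average the per-step costs. Step 0 is the cost
#' before any experiment and the final step the cost under full
#' identification; evaluation seeds are shared across policies so the curves
#' coincide exactly at both endpoints.
#'
#' @inheritParams run_benchmark
#' @param eval_exact evaluate per-step costs deterministically by backward
#'   accumulation instead of Monte-Carlo rollouts (noise-free curves).
#' @param policies selection policies to run (subset of `"optimal"`,
#'   `"approximate"`, `"random"`).
#' @param budget experiments per run (default: all `n_unknown`).
#' @return an object of class `sequential_benchmark`: list with `curves`
#'   (mean cost per step and policy) and `raw` (per-replicate step costs).
#' @export
sequential_benchmark <- function(n_networks = 10, n_truth = 4, n_unknown = 5,
                                 L = 0, n_genes = 6, k = 2, p = 0.01,
                                 control_gene = n_genes,
                                 undesirable = states_with_bits(n_genes, c(1, 2), c(0, 0)),
                                 zeta = 0.2, iterations = 4, delta = 0.3,
                                 M = 20, rollout_n = 1000, eval_n = 10000,
                                 horizon = 6, eval_exact = FALSE,
                                 policies = c("optimal", "approximate", "random"),
                                 budget = n_unknown, seed = 1) {
  policies <- match.arg(policies, several.ok = TRUE)
  problem <- control_problem(n_genes, control_gene, undesirable, zeta = zeta)
  cfg <- design_config("optimal", M = M, iterations = iterations,
                       delta = delta, rollout_n = rollout_n, horizon = horizon)
  rows <- list()
  for (w in seq_len(n_networks)) {
    net <- random_bnp(n = n_genes, k = k, p = p, seed = derive_seed(seed, w, 1L))
    P <- bnp_tpm(net)
    cpms <- cpms_from_tpm(P, net$regulators)
    local_seed(derive_seed(seed, w, 2L))
    sizes <- vapply(net$regulators, function(r) 2^length(r), numeric(1))
    pick <- sample.int(sum(sizes), n_unknown)
    base <- cumsum(c(0, sizes))
    gene <- findInterval(pick - 1, base[seq_len(n_genes)])
    unc0 <- uncertainty_class(gene = gene, context = pick - 1 - base[gene])
    for (v in seq_len(n_truth)) {
      local_seed(derive_seed(seed, w, v, 3L))
      phi <- stats::rbeta(n_unknown, unc0$alpha, unc0$beta)
      unc <- unc0
      if (L > 0) {
        true_tpm <- tpm_from_cpms(set_cpm_entries(cpms, unc0, phi))
        traj <- simulate_trajectory(true_tpm, L, seed = derive_seed(seed, w, v, 4L))
        unc <- update_posteriors(unc, traj, cpms$regulators, n_genes)
      }
      for (pol in policies) {
        run <- sequential_design(cpms, unc, problem, phi, cfg, budget = budget,
                                 policy = pol, eval_n = eval_n,
                                 eval_horizon = horizon,
                                 eval_iterations = iterations,
                                 eval_exact = eval_exact,
                                 seed = derive_seed(seed, w, v, 5L))
        rows[[length(rows) + 1]] <- data.frame(
          network = w, truth = v, policy = pol,
          step = run$steps$step, cost = run$steps$cost)
      }
    }
  }
  raw <- do.call(rbind, rows)
  curves <- stats::aggregate(cost ~ step + policy, data = raw, FUN = mean)
  structure(list(curves = curves, raw = raw,
                 settings = list(n_networks = n_networks, n_truth = n_truth,
                                 n_unknown = n_unknown, L = L, budget = budget,
                                 seed = seed)),
            class = "sequential_benchmark")
}

#' @export
print.sequential_benchmark <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Sequential-design curves: %d networks x %d truth sets, T = %d, L = %d\n",
              s$n_networks, s$n_truth, s$n_unknown, s$L))
  wide <- stats::reshape(x$curves, idvar = "step", timevar = "policy",
                         direction = "wide")
  names(wide) <- sub("^cost\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Write benchmark tables to TSV files
#'
#' @param bench a `design_benchmark`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "design_benchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("table1", "table2", "table3")) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(bench[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(settings = bench$settings,
         table2 = stats::setNames(as.list(bench$table2$mean_cost),
                                  bench$table2$policy)),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, summary_path))
}
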