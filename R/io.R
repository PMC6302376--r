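#' Read and write network, trajectory and uncertainty files
#'
#' File formats: networks are JSON objects with fields `n`, `gene_names`,
#' `regulators` (0-based index lists), `rule` (`type` `"truth_table"` with the
#' per-gene tables, or `"majority"` with the signed matrix) and `p`.
#' Trajectories are TSV with one decimal state per line. Uncertainty classes
#' are YAML lists of `{gene, context, alpha, beta, [value]}` records (1-based
#' gene, 0-based context).
#'
#' @param net a [boolean_network()].
#' @param path file path.
#' @return `load_network()` returns a `bnp`; save functions return the path
#'   invisibly.
#' @name grn_io
NULL

#' @rdname grn_io
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "bnp"))
  rule <- if (!is.null(net$regulatory_matrix)) {
    list(type = "majority",
         payload = apply(net$regulatory_matrix, 1, as.integer, simplify = FALSE))
  } else {
    list(type = "truth_table", payload = net$rules)
  }
  obj <- list(n = net$n, gene_names = net$gene_names,
              regulators = lapply(net$regulators, function(r) r - 1L),
              rule = rule, p = net$p)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname grn_io
#' @export
load_network <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed network JSON: ",
                                           conditionMessage(e), call. = FALSE))
  for (f in c("n", "regulators", "rule", "p")) {
    if (is.null(obj[[f]])) stop(sprintf("network JSON missing field '%s'", f),
                                call. = FALSE)
  }
  n <- obj$n
  regs <- lapply(as_index_list(obj$regulators, n), function(r) r + 1L)
  if (any(unlist(regs) < 1) || any(unlist(regs) > n)) {
    stop("network JSON: regulator index inconsistent with n", call. = FALSE)
  }
  if (identical(obj$rule$type, "majority")) {
    R <- do.call(rbind, as_index_list(obj$rule$payload, n))
    net <- boolean_network(
      regulators = regs,
      rules = lapply(seq_len(n), function(i) majority_truth_table(R, i, regs[[i]])),
      p = obj$p, gene_names = obj$gene_names, regulatory_matrix = R)
  } else if (identical(obj$rule$type, "truth_table")) {
    net <- boolean_network(regulators = regs,
                           rules = as_index_list(obj$rule$payload, n),
                           p = obj$p, gene_names = obj$gene_names)
  } else {
    stop("network JSON: rule type must be 'truth_table' or 'majority'",
         call. = FALSE)
  }
  net
}

# jsonlite may simplify a ragged/uniform list to a matrix; normalize to a list.
as_index_list <- function(x, n) {
  if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
  if (length(x) != n) stop("network JSON: per-gene list has wrong length", call. = FALSE)
  lapply(x, function(r) as.integer(unlist(r)))
}

#' @rdname grn_io
#' @param traj integer vector of decimal states.
#' @export
save_trajectory <- function(traj, path) {
  utils::write.table(data.frame(state = as.integer(traj)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @param n gene count used to validate the states.
#' @export
load_trajectory <- function(path, n = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.integer(trimws(lines)))
  bad <- which(is.na(vals) | vals < 0)
  if (!is.null(n)) bad <- union(bad, which(vals >= 2^n))
  if (length(bad) > 0) {
    stop(sprintf("trajectory file %s: invalid state on line %d ('%s')",
                 path, bad[1], lines[bad[1]]), call. = FALSE)
  }
  vals
}

#' @rdname grn_io
#' @param unc an [uncertainty_class()].
#' @export
save_uncertainty <- function(unc, path) {
  recs <- lapply(seq_len(nrow(unc)), function(q) {
    rec <- list(gene = unc$gene[q], context = unc$context[q],
                alpha = unc$alpha[q], beta = unc$beta[q])
    if (!is.na(unc$value[q])) rec$value <- unc$value[q]
    rec
  })
  yaml::write_yaml(list(parameters = recs), path)
  invisible(path)
}

#' @rdname grn_io
#' @export
load_uncertainty <- function(path) {
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed uncertainty YAML: ",
                                           conditionMessage(e), call. = FALSE))
  recs <- obj$parameters
  if (is.null(recs)) stop("uncertainty YAML: missing 'parameters' list", call. = FALSE)
  get_field <- function(f, default = NULL) {
    vapply(seq_along(recs), function(q) {
      v <- recs[[q]][[f]]
      if (is.null(v)) {
        if (is.null(default)) {
          stop(sprintf("uncertainty YAML: record %d missing field '%s'", q, f),
               call. = FALSE)
        }
        default
      } else as.numeric(v)
    }, numeric(1))
  }
  uncertainty_class(gene = get_field("gene"), context = get_field("context"),
                    alpha = get_field("alpha"), beta = get_field("beta"),
                    value = get_field("value", default = NA_real_))
}

#' Run a configured design pipeline and write its artifacts
#'
#' Orchestrates the full workflow from a configuration list (or YAML file):
#' load or generate a network, extract CPMs, blind the configured parameters,
#' optionally update priors from a trajectory, run sequential design, and
#' write the chosen experiments, per-step costs, the final IBR policy, and a
#' manifest of all seeds and settings.
#'
#' @param config named list or path to a YAML file. Recognized fields:
#'   `network` (path; or `n_genes`/`k`/`p` to generate one), `trajectory`
#'   (path, optional), `uncertainty` (path; or `n_unknown` to blind random
#'   rows), `control_gene`, `undesirable` (decimal states), `zeta`,
#'   `iterations`, `delta`, `method`, `M`, `budget`, `eval_n`, `horizon`,
#'   `seed`, `outdir`.
#' @return invisibly, the manifest list.
#' @export
run_design <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(f, default = NULL) if (is.null(config[[f]])) default else config[[f]]
  seed <- cfg("seed", 1)
  outdir <- cfg("outdir", ".")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  net <- if (!is.null(config$network)) load_network(config$network) else {
    random_bnp(n = cfg("n_genes", 6), k = cfg("k", 2), p = cfg("p", 0.01),
               seed = derive_seed(seed, 1L))
  }
  n <- net$n
  P <- bnp_tpm(net)
  cpms <- cpms_from_tpm(P, net$regulators)
  unc <- if (!is.null(config$uncertainty)) load_uncertainty(config$uncertainty) else {
    local_seed(derive_seed(seed, 2L))
    sizes <- vapply(cpms$regulators, function(r) 2^length(r), numeric(1))
    pick <- sample.int(sum(sizes), cfg("n_unknown", 5))
    gene <- findInterval(pick - 1, cumsum(c(0, sizes))[seq_len(n)], rightmost.closed = FALSE)
    offset <- pick - 1 - cumsum(c(0, sizes))[gene]
    uncertainty_class(gene = gene, context = offset)
  }
  # true values: the network's own extracted conditional probabilities
  true_values <- vapply(seq_len(nrow(unc)), function(q) {
    cpms$matrices[[unc$gene[q]]][unc$context[q] + 1L, 1]
  }, numeric(1))
  if (!is.null(config$trajectory)) {
    traj <- load_trajectory(config$trajectory, n = n)
    unc <- update_posteriors(unc, traj, cpms$regulators, n)
  }
  problem <- control_problem(
    n, cfg("control_gene", n),
    cfg("undesirable", states_with_bits(n, c(1, 2), c(0, 0))),
    zeta = cfg("zeta", 0.2))
  dcfg <- design_config(method = cfg("method", "optimal"), M = cfg("M", 20),
                        iterations = cfg("iterations", 4),
                        delta = cfg("delta", 0.3),
                        rollout_n = cfg("rollout_n", 1000),
                        horizon = cfg("horizon", 6))
  run <- sequential_design(
    cpms, unc, problem, true_values, dcfg,
    budget = cfg("budget", n_unknown(unc)),
    policy = if (dcfg$method == "optimal") "optimal" else "approximate",
    eval_n = cfg("eval_n", 10000), eval_horizon = cfg("horizon", 6),
    eval_iterations = cfg("iterations", 4), seed = derive_seed(seed, 3L))

  for (q in which(!is.na(run$steps$chosen))) {
    unc <- condition_on(unc, run$steps$chosen[q], true_values[run$steps$chosen[q]])
  }
  final_policy <- ibr_policy(effective_tpm(cpms, unc), problem,
                             iterations = cfg("iterations", 4))
  utils::write.table(run$steps, file.path(outdir, "design_steps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(actions = final_policy$actions, J = final_policy$J),
                       file.path(outdir, "policy.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = seed, n_genes = n, p = net$p,
                   budget = run$budget, method = dcfg$method,
                   settings = config[setdiff(names(config), "outdir")],
                   steps = run$steps$chosen[!is.na(run$steps$chosen)],
                   final_cost = mean(final_policy$J))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
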