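#' Boolean networks with perturbation (BNp)
#'
#' A BNp is a Boolean network whose genes each flip with a small perturbation
#' probability `p` per step, which makes the state sequence an ergodic Markov
#' chain. Update rules are truth tables over each gene's regulator context;
#' signed-majority-vote networks are compiled to truth tables at construction
#' and keep their regulatory matrix.
#'
#' @param regulators list of integer vectors: 1-based regulator indices per
#'   gene, ordered ascending (ordering induced from `X_1..X_n`).
#' @param rules list of binary vectors: per gene a truth table of length
#'   `2^k_i`, entry `j+1` giving the output for regulator context `j`
#'   (decimal, first regulator most significant).
#' @param p perturbation probability in `[0, 1)`.
#' @param gene_names optional character vector of gene identifiers.
#' @param regulatory_matrix optional signed matrix (entries -1/0/1) for
#'   majority-vote networks; kept for provenance.
#' @return An object of class `bnp`.
#' @seealso [random_bnp()], [cell_cycle_network()], [tp53_network()],
#'   [bnp_tpm()]
#' @export
boolean_network <- function(regulators, rules, p = 0.01, gene_names = NULL,
                            regulatory_matrix = NULL) {
  n <- length(regulators)
  if (length(rules) != n) stop("need one rule per gene", call. = FALSE)
  if (p < 0 || p >= 1) stop("perturbation probability must be in [0, 1)", call. = FALSE)
  if (is.null(gene_names)) gene_names <- paste0("X", seq_len(n))
  for (i in seq_len(n)) {
    reg <- regulators[[i]]
    if (anyDuplicated(reg) || any(reg < 1) || any(reg > n)) {
      stop(sprintf("gene %d: regulator indices must be distinct and in 1..%d", i, n),
           call. = FALSE)
    }
    if (is.null(rules[[i]])) stop(sprintf("gene %d: rule missing", i), call. = FALSE)
    if (length(rules[[i]]) != 2^length(reg)) {
      stop(sprintf("gene %d: truth table must have length 2^k = %d",
                   i, 2^length(reg)), call. = FALSE)
    }
    if (!all(rules[[i]] %in% c(0, 1))) {
      stop(sprintf("gene %d: truth-table outputs must be binary", i), call. = FALSE)
    }
    regulators[[i]] <- as.integer(reg)
    rules[[i]] <- as.integer(rules[[i]])
  }
  structure(
    list(n = n, gene_names = gene_names, regulators = regulators,
         rules = rules, p = p, regulatory_matrix = regulatory_matrix),
    class = "bnp"
  )
}

#' @export
print.bnp <- function(x, ...) {
  cat(sprintf("Boolean network with perturbation: %d genes, p = %g\n", x$n, x$p))
  k <- vapply(x$regulators, length, integer(1))
  cat(sprintf("  genes: %s\n", paste(x$gene_names, collapse = ", ")))
  cat(sprintf("  in-degrees: %s\n", paste(k, collapse = " ")))
  if (!is.null(x$regulatory_matrix)) cat("  rule origin: signed majority vote\n")
  invisible(x)
}

#' Deterministic next state of a Boolean network
#'
#' Applies the noise-free transition rule `X(t+1) = F(X(t))`.
#'
#' @param net a [boolean_network()].
#' @param s decimal state(s) in `0:(2^n - 1)`.
#' @return next decimal state(s).
#' @export
next_state <- function(net, s) {
  stopifnot(inherits(net, "bnp"))
  n <- net$n
  if (any(s < 0) || any(s >= 2^n)) stop("state out of range", call. = FALSE)
  out <- numeric(length(s))
  for (i in seq_len(n)) {
    ctx <- context_of_states(s, net$regulators[[i]], n)
    out <- out * 2 + net$rules[[i]][ctx + 1L]
  }
  out
}

#' Signed majority-vote update
#'
#' One synchronous step of the majority-vote rule: gene `i` becomes 1 when the
#' signed input sum \eqn{\sum_j R_{ij} X_j(t)} is positive, 0 when negative,
#' and keeps its value when the sum is zero.
#'
#' @param R signed regulatory matrix (`n x n`, entries -1/0/1); `R[i, j]`
#'   nonzero means gene `j` regulates gene `i` (positive = activation).
#' @param s decimal state in `0:(2^n - 1)`.
#' @return next decimal state.
#' @export
next_state_majority <- function(R, s) {
  n <- nrow(R)
  stopifnot(ncol(R) == n, all(R %in% c(-1, 0, 1)))
  x <- state_decode(s, n)
  v <- as.numeric(R %*% x)
  state_encode(ifelse(v > 0, 1, ifelse(v < 0, 0, x)))
}

# Truth table for gene i of a majority-vote network whose regulators are
# nonzero entries of R[i, ] plus gene i itself (the tie branch depends on X_i).
majority_regulators <- function(R, i) {
  sort(unique(c(i, which(R[i, ] != 0))))
}

majority_truth_table <- function(R, i, regulators) {
  k <- length(regulators)
  tab <- integer(2^k)
  for (ctx in 0:(2^k - 1)) {
    bits <- state_decode(ctx, k)          # regulator values, ascending order
    v <- sum(R[i, regulators] * bits)
    self <- bits[match(i, regulators)]
    tab[ctx + 1L] <- if (v > 0) 1L else if (v < 0) 0L else as.integer(self)
  }
  tab
}

#' Random Boolean network with perturbation
#'
#' Generates a random BNp following the synthetic-network protocol: each gene
#' receives `k` distinct regulators drawn uniformly from all genes
#' (self-regulation allowed), a bias `b` is drawn from a beta distribution with
#' the given mean and variance, and every truth-table output is an independent
#' Bernoulli(`b`).
#'
#' @param n gene count (default 6).
#' @param k regulators per gene (default 2).
#' @param bias_mean,bias_var mean and variance of the beta distribution from
#'   which each gene's truth-table bias is drawn (defaults 0.5 and 1e-4).
#' @param p perturbation probability (default 0.01).
#' @param seed optional integer seed for reproducible generation.
#' @return a [boolean_network()].
#' @export
random_bnp <- function(n = 6, k = 2, bias_mean = 0.5, bias_var = 1e-4,
                       p = 0.01, seed = NULL) {
  if (k >= n) stop("k must be < n (regulators are distinct genes)", call. = FALSE)
  ab <- beta_shapes_from_moments(bias_mean, bias_var)
  local_seed(seed)
  regulators <- vector("list", n)
  rules <- vector("list", n)
  for (i in seq_len(n)) {
    regulators[[i]] <- sort(sample.int(n, k))
    b <- stats::rbeta(1, ab[1], ab[2])
    rules[[i]] <- stats::rbinom(2^k, 1, b)
  }
  boolean_network(regulators, rules, p = p)
}

# Solve mean/variance for beta shape parameters; for mean 0.5 and variance
# 1/(4(2a+1)) this gives the symmetric pair a = b.
beta_shapes_from_moments <- function(m, v) {
  if (m <= 0 || m >= 1) stop("bias mean must be in (0, 1)", call. = FALSE)
  if (v <= 0 || v >= m * (1 - m)) stop("bias variance out of range", call. = FALSE)
  nu <- m * (1 - m) / v - 1
  c(alpha = m * nu, beta = (1 - m) * nu)
}

#' Transition probability matrix of a BNp
#'
#' Perturbation is applied to the deterministic image: the next state is
#' `F(X(t))` with probability \eqn{(1-p)^n}, otherwise `F(X(t)) XOR gamma` with
#' gamma drawn gene-wise Bernoulli(`p`) conditioned nonzero. The two branches
#' combine to the closed form \eqn{P_{ij} = (1-p)^{n-d} p^d} with `d` the
#' Hamming distance between `j` and `F(i)`; rows sum to one exactly by the
#' binomial theorem. For `p > 0` every entry is positive, so the chain has a
#' unique steady-state distribution.
#'
#' @param net a [boolean_network()].
#' @return a `2^n x 2^n` row-stochastic matrix (states 0-based in row/column
#'   order).
#' @export
bnp_tpm <- function(net) {
  stopifnot(inherits(net, "bnp"))
  n <- net$n
  S <- 2^n
  p <- net$p
  f <- next_state(net, 0:(S - 1))
  pc <- popcount_table(n)
  d <- matrix(0L, S, S)
  for (i in seq_len(S)) {
    d[i, ] <- pc[bitwXor(f[i], 0:(S - 1)) + 1L]
  }
  P <- (1 - p)^(n - d) * p^d
  # p = 0 collapses 0^0 correctly to 1 on the diagonal image
  if (p == 0) {
    P <- matrix(0, S, S)
    P[cbind(seq_len(S), f + 1L)] <- 1
  }
  P
}

#' Steady-state distribution of a transition probability matrix
#'
#' Solves \eqn{\pi^T = \pi^T P} with \eqn{\sum_i \pi_i = 1} by a dense linear
#' solve. Requires the chain to be irreducible (guaranteed for a BNp with
#' `p > 0`).
#'
#' @param P row-stochastic square matrix.
#' @param tol residual tolerance for the stationarity check.
#' @return probability vector over states.
#' @export
steady_state <- function(P, tol = 1e-10) {
  S <- nrow(P)
  stopifnot(ncol(P) == S)
  A <- t(P) - diag(S)
  A[S, ] <- 1                      # replace one equation with normalization
  b <- c(rep(0, S - 1), 1)
  pi <- tryCatch(solve(A, b), error = function(e) {
    stop("steady-state solve failed (reducible chain?): ", conditionMessage(e),
         call. = FALSE)
  })
  if (max(abs(as.numeric(pi %*% P) - pi)) > max(tol, 1e-8)) {
    stop("steady-state residual too large; chain may be reducible", call. = FALSE)
  }
  pi[abs(pi) < .Machine$double.eps] <- 0
  pi / sum(pi)
}

#' Simulate a state trajectory from a transition matrix
#'
#' @param P row-stochastic transition matrix over `2^n` states.
#' @param steps number of transitions `L`; the returned trajectory has
#'   `steps + 1` states.
#' @param init initial decimal state; drawn uniformly when `NULL`.
#' @param seed optional integer seed.
#' @return integer vector of decimal states, length `steps + 1`.
#' @export
simulate_trajectory <- function(P, steps, init = NULL, seed = NULL) {
  S <- nrow(P)
  local_seed(seed)
  s <- if (is.null(init)) sample.int(S, 1) - 1L else as.integer(init)
  stopifnot(s >= 0, s < S)
  out <- integer(steps + 1)
  out[1] <- s
  if (steps > 0) {
    for (t in seq_len(steps)) {
      s <- sample.int(S, 1, prob = P[s + 1L, ]) - 1L
      out[t + 1] <- s
    }
  }
  out
}

#' Simulate method for BNp objects
#'
#' Draws a state trajectory of `nsim` transitions from the network's
#' perturbed Markov chain.
#'
#' @param object a [boolean_network()].
#' @param nsim number of transitions.
#' @param seed optional integer seed.
#' @param init optional initial state.
#' @param ... unused.
#' @return integer vector of decimal states, length `nsim + 1`.
#' @export
simulate.bnp <- function(object, nsim = 1, seed = NULL, init = NULL, ...) {
  simulate_trajectory(bnp_tpm(object), steps = nsim, init = init, seed = seed)
}
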