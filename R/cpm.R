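#' Conditional probability matrix sets
#'
#' A Markovian regulatory network with per-gene regulator sets is completely
#' described by `n` conditional probability matrices (CPMs). The CPM of gene
#' `X_i` has `2^k_i` rows, one per decimal regulator context `j`, and two
#' columns: `Pr[X_i = 0 | context j]` and `Pr[X_i = 1 | context j]`.
#'
#' @param matrices list of `2^k_i x 2` row-stochastic matrices, one per gene.
#' @param regulators list of 1-based regulator index vectors (ascending).
#' @return an object of class `cpm_set`.
#' @export
cpm_set <- function(matrices, regulators) {
  n <- length(matrices)
  if (length(regulators) != n) stop("one regulator set per gene required", call. = FALSE)
  for (i in seq_len(n)) {
    M <- matrices[[i]]
    k <- length(regulators[[i]])
    if (!is.matrix(M) || nrow(M) != 2^k || ncol(M) != 2) {
      stop(sprintf("gene %d: CPM must be %d x 2", i, 2^k), call. = FALSE)
    }
    if (any(M < -1e-12) || any(M > 1 + 1e-12)) {
      stop(sprintf("gene %d: CPM entries must lie in [0, 1]", i), call. = FALSE)
    }
    if (max(abs(rowSums(M) - 1)) > 1e-10) {
      stop(sprintf("gene %d: CPM rows must sum to 1", i), call. = FALSE)
    }
  }
  structure(list(n = n, matrices = matrices,
                 regulators = lapply(regulators, as.integer)),
            class = "cpm_set")
}

#' @export
print.cpm_set <- function(x, ...) {
  k <- vapply(x$regulators, length, integer(1))
  cat(sprintf("CPM set: %d genes, CPM sizes %s\n", x$n,
              paste(2^k, "x 2", collapse = ", ")))
  invisible(x)
}

#' Build a transition probability matrix from CPMs
#'
#' Genes are conditionally independent given the full current state, so the
#' TPM factorizes over genes:
#' \eqn{P_{ij} = \prod_k C_{\Gamma_k[i],\, j_k + 1}(X_k)}, where
#' \eqn{\Gamma_k[i]} is the decimal regulator context of gene `k` in source
#' state `i` and \eqn{j_k} is gene `k`'s bit in target state `j`.
#'
#' @param cpms a [cpm_set()].
#' @return a `2^n x 2^n` row-stochastic matrix.
#' @export
tpm_from_cpms <- function(cpms) {
  stopifnot(inherits(cpms, "cpm_set"))
  n <- cpms$n
  S <- 2^n
  states <- 0:(S - 1)
  P <- matrix(1, S, S)
  for (k in seq_len(n)) {
    P <- P * gene_factor(cpms$matrices[[k]], cpms$regulators[[k]], k, n)
  }
  P
}

# S x S factor of one gene in the TPM product: entry (i, j) is the gene's
# conditional probability of taking its bit in target j given its regulator
# context in source i.
gene_factor <- function(Ck, regulators, k, n) {
  states <- 0:(2^n - 1)
  ctx <- context_of_states(states, regulators, n)   # per source state
  bit <- gene_bit(states, k, n)                     # per target state
  Ck[ctx + 1L, bit + 1L, drop = FALSE]
}

#' Extract CPMs from a transition probability matrix
#'
#' Inverts the factorization gene by gene:
#' `Pr[X_i = 0 | context j]` is the total mass each TPM row assigns to target
#' states with `X_i = 0`, averaged (unweighted by default) over the source
#' states whose regulator context equals `j`. For a TPM that genuinely
#' factorizes over genes (any BNp TPM) the recovery is exact.
#'
#' @param P row-stochastic `2^n x 2^n` matrix.
#' @param regulators list of 1-based regulator index vectors per gene.
#' @param weights `"uniform"` for the plain average over matching source rows,
#'   or `"steady_state"` to weight rows by the chain's stationary probability.
#' @return a [cpm_set()].
#' @export
cpms_from_tpm <- function(P, regulators, weights = c("uniform", "steady_state")) {
  weights <- match.arg(weights)
  S <- nrow(P)
  n <- as.integer(round(log2(S)))
  stopifnot(2^n == S, ncol(P) == S, length(regulators) == n)
  states <- 0:(S - 1)
  w <- if (weights == "steady_state") steady_state(P) else rep(1, S)
  mats <- vector("list", n)
  for (i in seq_len(n)) {
    ctx <- context_of_states(states, regulators[[i]], n)
    zero_mass <- as.numeric(P %*% (gene_bit(states, i, n) == 0))
    k <- length(regulators[[i]])
    M <- matrix(NA_real_, 2^k, 2)
    for (j in 0:(2^k - 1)) {
      rows <- which(ctx == j)
      if (length(rows) == 0) {
        stop(sprintf("gene %d: regulator context %d unrepresented among states", i, j),
             call. = FALSE)
      }
      c0 <- sum(w[rows] * zero_mass[rows]) / sum(w[rows])
      M[j + 1L, ] <- c(c0, 1 - c0)
    }
    mats[[i]] <- M
  }
  cpm_set(mats, regulators)
}
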