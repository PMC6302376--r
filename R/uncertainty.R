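#' Uncertainty class over conditional probabilities
#'
#' Each unknown conditional probability \eqn{\theta_i} parametrizes one CPM
#' row: \eqn{\theta_i = Pr[X_i = 0 | \Gamma = j]} (the row's second column is
#' its complement, since CPM rows sum to one). Unknowns are independent with
#' conjugate `Beta(alpha, beta)` priors; observing a state trajectory adds the
#' per-context outcome counts to the hyperparameters. A parameter may carry a
#' revealed value `phi` once its experiment has been performed, which removes
#' it from the active (unrevealed) set.
#'
#' @param gene integer vector of gene indices (1-based).
#' @param context integer vector of decimal regulator contexts (0-based, first
#'   regulator most significant), one per parameter.
#' @param alpha,beta positive beta hyperparameters (recycled; default
#'   `Beta(1, 1)`, uniform).
#' @param value optional revealed values in `[0, 1]` (`NA` = unrevealed).
#' @return an object of class `uncertainty_class`: a data frame with columns
#'   `gene`, `context`, `alpha`, `beta`, `value`.
#' @export
uncertainty_class <- function(gene, context, alpha = 1, beta = 1, value = NA_real_) {
  Tn <- length(gene)
  stopifnot(length(context) == Tn)
  u <- data.frame(gene = as.integer(gene), context = as.integer(context),
                  alpha = rep_len(as.numeric(alpha), Tn),
                  beta = rep_len(as.numeric(beta), Tn),
                  value = rep_len(as.numeric(value), Tn))
  if (any(u$alpha <= 0) || any(u$beta <= 0)) {
    stop("beta hyperparameters must be positive", call. = FALSE)
  }
  if (anyDuplicated(u[c("gene", "context")])) {
    stop("no two parameters may address the same (gene, context) CPM row", call. = FALSE)
  }
  if (any(!is.na(u$value) & (u$value < 0 | u$value > 1))) {
    stop("revealed values must lie in [0, 1]", call. = FALSE)
  }
  class(u) <- c("uncertainty_class", "data.frame")
  u
}

#' @export
print.uncertainty_class <- function(x, ...) {
  cat(sprintf("Uncertainty class: %d parameter(s), %d unrevealed\n",
              nrow(x), sum(is.na(x$value))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Number of unrevealed parameters
#' @param unc an [uncertainty_class()].
#' @return integer count `T` of parameters still unknown.
#' @export
n_unknown <- function(unc) sum(is.na(unc$value))

#' Posterior means of the unknown parameters
#' @param unc an [uncertainty_class()].
#' @return numeric vector `alpha / (alpha + beta)` (revealed parameters return
#'   their revealed value).
#' @export
posterior_mean <- function(unc) {
  ifelse(is.na(unc$value), unc$alpha / (unc$alpha + unc$beta), unc$value)
}

#' Conjugate posterior update from a state trajectory
#'
#' For each unrevealed parameter at (gene `i`, context `j`), every transition
#' `l -> l+1` whose source state has regulator context `j` for gene `i` adds 1
#' to `alpha` when `X_i(l+1) = 0` and 1 to `beta` when `X_i(l+1) = 1`.
#'
#' @param unc an [uncertainty_class()].
#' @param traj integer vector of decimal states (length `L + 1` for `L`
#'   transitions).
#' @param regulators list of regulator index vectors per gene.
#' @param n gene count.
#' @return the updated [uncertainty_class()].
#' @export
update_posteriors <- function(unc, traj, regulators, n) {
  if (any(traj < 0) || any(traj >= 2^n)) {
    stop("trajectory states out of range for the state space", call. = FALSE)
  }
  L <- length(traj) - 1
  if (L <= 0) return(unc)
  src <- traj[seq_len(L)]
  dst <- traj[seq_len(L) + 1]
  for (q in seq_len(nrow(unc))) {
    if (!is.na(unc$value[q])) next
    i <- unc$gene[q]
    ctx <- context_of_states(src, regulators[[i]], n)
    hit <- ctx == unc$context[q]
    bits <- gene_bit(dst[hit], i, n)
    unc$alpha[q] <- unc$alpha[q] + sum(bits == 0)
    unc$beta[q] <- unc$beta[q] + sum(bits == 1)
  }
  unc
}

#' Condition the class on an experiment outcome
#'
#' Fixes parameter `index` to `value` (the experiment's revealed conditional
#' probability), removing it from the active set; the prior over the remaining
#' parameters is the product of their beta distributions.
#'
#' @param unc an [uncertainty_class()].
#' @param index row index of the parameter.
#' @param value revealed probability in `[0, 1]`.
#' @return the reduced [uncertainty_class()].
#' @export
condition_on <- function(unc, index, value) {
  if (index < 1 || index > nrow(unc)) stop("parameter index out of range", call. = FALSE)
  if (value < 0 || value > 1) stop("revealed value must lie in [0, 1]", call. = FALSE)
  unc$value[index] <- value
  unc
}

#' Draw a full CPM realization from the uncertainty class
#'
#' Each unrevealed parameter is drawn independently from its beta
#' distribution; revealed parameters use their revealed value; known CPM
#' entries are used as-is.
#'
#' @param cpms base [cpm_set()] (entries at unknown positions are ignored).
#' @param unc an [uncertainty_class()].
#' @param seed optional integer seed.
#' @return a [cpm_set()] realization.
#' @export
sample_theta <- function(cpms, unc, seed = NULL) {
  local_seed(seed)
  th <- ifelse(is.na(unc$value),
               stats::rbeta(nrow(unc), unc$alpha, unc$beta),
               unc$value)
  set_cpm_entries(cpms, unc, th)
}

# Overwrite the parametrized CPM rows with given Pr[X_i = 0] values.
set_cpm_entries <- function(cpms, unc, theta) {
  for (q in seq_len(nrow(unc))) {
    i <- unc$gene[q]
    j <- unc$context[q] + 1L
    if (j < 1 || j > nrow(cpms$matrices[[i]])) {
      stop(sprintf("parameter %d references a nonexistent CPM row", q), call. = FALSE)
    }
    cpms$matrices[[i]][j, ] <- c(theta[q], 1 - theta[q])
  }
  cpms
}

#' Effective transition probability matrix (ETPM)
#'
#' The expectation of the uncertain TPM over the (posterior) product-beta
#' prior. Because the parameters are independent and the TPM factorizes over
#' genes, the expectation passes inside the product: each unknown CPM entry is
#' replaced by its posterior mean (revealed parameters by their value), and
#' the TPM is rebuilt from the resulting CPMs. The ETPM represents the whole
#' uncertainty class for control: the IBR policy is the optimal policy of the
#' ETPM.
#'
#' @param cpms base [cpm_set()].
#' @param unc an [uncertainty_class()] (may have zero rows).
#' @return a row-stochastic `2^n x 2^n` matrix.
#' @export
effective_tpm <- function(cpms, unc) {
  if (nrow(unc) > 0) cpms <- set_cpm_entries(cpms, unc, posterior_mean(unc))
  tpm_from_cpms(cpms)
}
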