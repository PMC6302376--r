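#' Mean first passage times between phenotype blocks
#'
#' Partitioning the TPM into desirable/undesirable blocks
#' \eqn{P_{DD}, P_{DU}, P_{UD}, P_{UU}}, the vectors of expected hitting times
#' satisfy \eqn{K_{DU} = e + P_{DD} K_{DU}} and \eqn{K_{UD} = e + P_{UU} K_{UD}},
#' solved here as dense linear systems. Finiteness requires the spectral
#' radius of the diagonal blocks to be below one (guaranteed for a strictly
#' positive TPM).
#'
#' @param P row-stochastic TPM.
#' @param problem a [control_problem()] supplying the D/U partition (or pass
#'   `desirable`/`undesirable` explicitly).
#' @param desirable,undesirable optional explicit decimal state sets.
#' @return an object of class `mfpt_result`: list with `K_DU` (named by
#'   desirable states) and `K_UD` (named by undesirable states), plus the full
#'   hitting-time vectors `h_U`, `h_D` over all states (zero on the target
#'   set), used for the control policy.
#' @export
mfpt_vectors <- function(P, problem = NULL, desirable = NULL, undesirable = NULL) {
  S <- nrow(P)
  if (!is.null(problem)) {
    desirable <- problem$desirable
    undesirable <- problem$undesirable
  }
  stopifnot(length(desirable) > 0, length(undesirable) > 0)
  if (length(intersect(desirable, undesirable)) > 0 ||
      length(union(desirable, undesirable)) != S) {
    stop("desirable/undesirable must partition the state space", call. = FALSE)
  }
  Didx <- desirable + 1L
  Uidx <- undesirable + 1L
  K_DU <- solve_block(P[Didx, Didx, drop = FALSE], desirable, "undesirable")
  K_UD <- solve_block(P[Uidx, Uidx, drop = FALSE], undesirable, "desirable")
  h_U <- numeric(S)   # hitting time of U from every state (0 on U)
  h_D <- numeric(S)
  h_U[Didx] <- K_DU
  h_D[Uidx] <- K_UD
  structure(
    list(K_DU = stats::setNames(K_DU, desirable),
         K_UD = stats::setNames(K_UD, undesirable),
         h_U = h_U, h_D = h_D,
         desirable = desirable, undesirable = undesirable),
    class = "mfpt_result"
  )
}

solve_block <- function(B, states, target) {
  m <- nrow(B)
  K <- tryCatch(solve(diag(m) - B, rep(1, m)), error = function(e) NULL)
  if (is.null(K) || any(!is.finite(K)) || any(K < 1 - 1e-9)) {
    stop(sprintf(
      "first-passage system is singular: states {%s} cannot reach the %s set",
      paste(states, collapse = ","), target), call. = FALSE)
  }
  K
}

#' @export
print.mfpt_result <- function(x, ...) {
  cat(sprintf("MFPT vectors: |D| = %d, |U| = %d\n",
              length(x$K_DU), length(x$K_UD)))
  cat(sprintf("  K_DU range [%.3g, %.3g], K_UD range [%.3g, %.3g]\n",
              min(x$K_DU), max(x$K_DU), min(x$K_UD), max(x$K_UD)))
  invisible(x)
}

#' MFPT-based stationary control policy
#'
#' For a desirable state, intervene when flipping the control gene increases
#' the expected time to reach the undesirable set by more than `delta`; for an
#' undesirable state, intervene when flipping decreases the expected time to
#' reach the desirable set by more than `delta`. When the flipped partner lies
#' in the opposite block the comparison uses the full hitting-time vector for
#' the relevant target set (zero on the target set itself), which restricts to
#' `K_DU`/`K_UD` on their blocks; this keeps the "reach desirable, leave
#' undesirable quickly" comparison well defined for every state.
#'
#' @param P TPM (or ETPM) from which the MFPTs are computed (uncontrolled).
#' @param problem a [control_problem()] (control gene and D/U partition).
#' @param delta nonnegative improvement threshold (default 0.3).
#' @return a `grn_policy` (no cost vector; `J` is `NULL`).
#' @export
mfpt_policy <- function(P, problem, delta = 0.3) {
  stopifnot(delta >= 0)
  S <- problem$S
  n <- problem$n
  g <- problem$control_gene
  mf <- mfpt_vectors(P, problem)
  states <- 0:(S - 1)
  flip <- flip_gene(states, g, n)
  actions <- integer(S)
  inD <- states %in% problem$desirable
  actions[inD] <- as.integer(mf$h_U[flip[inD] + 1L] - mf$h_U[states[inD] + 1L] > delta)
  actions[!inD] <- as.integer(mf$h_D[states[!inD] + 1L] - mf$h_D[flip[!inD] + 1L] > delta)
  structure(
    list(actions = actions, J = NULL, residual = NA_real_, iterations = 0L,
         zeta = problem$zeta, control_gene = g, delta = delta),
    class = "grn_policy"
  )
}

#' MFPT approximation of the IBR policy
#'
#' The IBR policy is the optimal policy of the effective TPM, so its MFPT
#' approximation is the MFPT policy computed on the ETPM. Used to cut the cost
#' of experimental-design scoring; the policy finally implemented on the
#' network is always the exact IBR policy from value iteration.
#'
#' @param etpm effective TPM from [effective_tpm()].
#' @inheritParams mfpt_policy
#' @return a `grn_policy`.
#' @export
approx_ibr_policy <- function(etpm, problem, delta = 0.3) {
  mfpt_policy(etpm, problem, delta = delta)
}
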