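#' State-space encoding utilities
#'
#' Network states are gene activity profiles (GAPs): binary vectors
#' \eqn{(X_1,\dots,X_n)} encoded as decimal states \eqn{s \in \{0,\dots,2^n-1\}}
#' with gene \eqn{X_1} as the most significant bit. All user-facing state values
#' (trajectories, undesirable-state sets, policy indices) use this 0-based
#' decimal convention.
#'
#' @param x binary vector (values 0/1), gene 1 first.
#' @param s decimal state(s) in `0:(2^n - 1)`.
#' @param n gene count.
#' @return `state_encode()` returns a decimal state; `state_decode()` a binary
#'   vector (or matrix with one row per state when `s` has length > 1).
#' @examples
#' state_encode(c(1, 0, 0))  # X1 is the MSB: 4
#' state_decode(4, 3)
#' @export
state_encode <- function(x) {
  if (!all(x %in% c(0, 1))) stop("state vector must be binary", call. = FALSE)
  n <- length(x)
  sum(x * 2^(n - seq_len(n)))
}

#' @rdname state_encode
#' @export
state_decode <- function(s, n) {
  stopifnot(all(s >= 0), all(s < 2^n))
  out <- t(vapply(s, function(si) (si %/% 2^(n - seq_len(n))) %% 2, numeric(n)))
  if (length(s) == 1L) drop(out) else out
}

#' @rdname state_encode
#' @param i gene index (1-based).
#' @export
gene_bit <- function(s, i, n) {
  (s %/% 2^(n - i)) %% 2
}

#' @rdname state_encode
#' @param g gene whose bit is flipped.
#' @export
flip_gene <- function(s, g, n) {
  b <- gene_bit(s, g, n)
  s + (1 - 2 * b) * 2^(n - g)
}

# Bit-count lookup for all states 0..2^n-1 (used for perturbation kernels).
popcount_table <- function(n) {
  S <- 2^n
  pc <- integer(S)
  if (S > 1) for (s in 1:(S - 1)) pc[s + 1] <- pc[s %/% 2 + 1] + s %% 2
  pc
}

# Decimal regulator context of each source state for one gene.
# regulators are 1-based gene indices ordered ascending (ordering induced from
# X_1..X_n); the first regulator is the most significant bit of the context.
context_of_states <- function(states, regulators, n) {
  k <- length(regulators)
  ctx <- integer(length(states))
  for (r in seq_len(k)) {
    ctx <- ctx * 2L + as.integer(gene_bit(states, regulators[r], n))
  }
  ctx
}
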