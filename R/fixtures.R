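#' Mutated mammalian cell-cycle network
#'
#' Nine-gene Boolean model of the mammalian cell cycle with gene p27
#' permanently down-regulated (the "mutated" variant in which the cycle can
#' run without external growth stimuli). Genes, in index order:
#' CycD, Rb, E2F, CycE, Cdc20, Cdh1, UbcH10, CycB, CycA. CycD is an
#' extracellular signal with no Boolean function of its own and is modelled as
#' a held bit (identity rule) subject to the usual perturbation. States with
#' CycD and Rb both down-regulated (`X1 = 0`, `X2 = 0`) are the undesirable
#' phenotype; CycA (`X9`) is the conventional control gene.
#'
#' @param p perturbation probability (default 0.01).
#' @return a [boolean_network()] with 9 genes.
#' @export
cell_cycle_network <- function(p = 0.01) {
  genes <- c("CycD", "Rb", "E2F", "CycE", "Cdc20", "Cdh1", "UbcH10", "CycB", "CycA")
  # Boolean functions over the full state; x is the binary GAP (X1..X9)
  fns <- list(
    CycD   = function(x) x[1],
    Rb     = function(x) (!x[1] && !x[4] && !x[9] && !x[8]),
    E2F    = function(x) (!x[2] && !x[9] && !x[8]),
    CycE   = function(x) (x[3] && !x[2]),
    Cdc20  = function(x) x[8],
    Cdh1   = function(x) ((!x[9] && !x[8]) || x[5]),
    UbcH10 = function(x) (!x[6] || (x[6] && x[7] && (x[5] || x[9] || x[8]))),
    CycB   = function(x) (!x[5] && !x[6]),
    CycA   = function(x) ((x[3] && !x[2] && !x[5] && (!x[6] && !x[7])) ||
                          (x[9] && !x[2] && !x[5] && !(x[6] && x[7])))
  )
  regulators <- list(
    1L, c(1L, 4L, 8L, 9L), c(2L, 8L, 9L), c(2L, 3L), 8L,
    c(5L, 8L, 9L), c(5L, 6L, 7L, 8L, 9L), c(5L, 6L), c(2L, 3L, 5L, 6L, 7L, 9L)
  )
  rules <- truth_tables_from_functions(fns, regulators, n = 9)
  boolean_network(regulators, rules, p = p, gene_names = genes)
}

#' TP53 double-strand-break response network
#'
#' Six-node majority-vote Boolean model of the pathways regulating the tumour
#' suppressor TP53 after DNA double-strand breaks. Nodes, in index order:
#' DNA_DSBs, MDM2, TP53, WIP1, CHK2, ATM. Dynamics follow the signed
#' majority-vote rule ([next_state_majority()]); DNA_DSBs is an input signal
#' with no regulators (held bit). The undesirable phenotype is damage present
#' with MDM2 up and TP53 down (`X1 = 1`, `X2 = 1`, `X3 = 0`, decimal states
#' 48..55); ATM (`X6`) is the conventional control gene.
#'
#' The default regulatory matrix is a reconstruction of the published
#' ATM/CHK2/TP53/WIP1/MDM2 signalling logic (DSB activates ATM; ATM activates
#' CHK2 and TP53 and represses MDM2; CHK2 activates TP53; TP53 induces WIP1
#' and MDM2; WIP1 feeds back negatively on ATM, CHK2 and TP53 and positively
#' on MDM2). It is a synthetic stand-in for the published wiring diagram and
#' can be overridden via `R`.
#'
#' @param R optional 6x6 signed regulatory matrix (entries -1/0/1), rows =
#'   targets, columns = sources, index order as above.
#' @param p perturbation probability (default 0.01).
#' @return a [boolean_network()] with 6 genes.
#' @export
tp53_network <- function(R = NULL, p = 0.01) {
  genes <- c("DNA_DSBs", "MDM2", "TP53", "WIP1", "CHK2", "ATM")
  if (is.null(R)) {
    R <- matrix(0L, 6, 6, dimnames = list(genes, genes))
    R["MDM2", "TP53"] <- 1L
    R["MDM2", "WIP1"] <- 1L
    R["MDM2", "ATM"]  <- -1L
    R["TP53", "MDM2"] <- -1L
    R["TP53", "WIP1"] <- -1L
    R["TP53", "CHK2"] <- 1L
    R["TP53", "ATM"]  <- 1L
    R["WIP1", "TP53"] <- 1L
    R["CHK2", "ATM"]  <- 1L
    R["CHK2", "WIP1"] <- -1L
    R["ATM", "DNA_DSBs"] <- 1L
    R["ATM", "WIP1"]     <- -1L
  }
  if (!is.matrix(R) || nrow(R) != 6 || ncol(R) != 6 || !all(R %in% c(-1, 0, 1))) {
    stop("R must be a 6x6 signed matrix with entries in {-1, 0, 1}", call. = FALSE)
  }
  regulators <- lapply(1:6, function(i) majority_regulators(R, i))
  rules <- lapply(1:6, function(i) majority_truth_table(R, i, regulators[[i]]))
  boolean_network(regulators, rules, p = p, gene_names = genes,
                  regulatory_matrix = R)
}

# Compile full-state Boolean functions into per-gene truth tables over
# regulator contexts, verifying the declared regulator sets are sufficient.
truth_tables_from_functions <- function(fns, regulators, n) {
  lapply(seq_len(n), function(i) {
    reg <- regulators[[i]]
    k <- length(reg)
    tab <- integer(2^k)
    for (ctx in 0:(2^k - 1)) {
      bits <- state_decode(ctx, k)
      x <- numeric(n)                 # non-regulators cannot matter
      x[reg] <- bits
      tab[ctx + 1L] <- as.integer(fns[[i]](x))
    }
    tab
  })
}

#' Undesirable-state helper
#'
#' Decimal states whose named gene bits take the given values, e.g. the
#' synthetic-benchmark set `X1 = 0, X2 = 0` or the TP53 set
#' `X1 = 1, X2 = 1, X3 = 0`.
#'
#' @param n gene count.
#' @param genes gene indices constrained.
#' @param values required bit values (same length as `genes`).
#' @return sorted vector of decimal states.
#' @export
states_with_bits <- function(n, genes, values) {
  stopifnot(length(genes) == length(values))
  s <- 0:(2^n - 1)
  keep <- rep(TRUE, length(s))
  for (q in seq_along(genes)) keep <- keep & gene_bit(s, genes[q], n) == values[q]
  s[keep]
}
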