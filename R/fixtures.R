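#' Two-spin oracle fixture
#'
#' The exactly solvable two-spin ferromagnet at dimensionless coupling
#' `beta * J`: pair correlation `tanh(bJ)`, connected correlation matrix,
#' the exact naive mean-field inversion value `t / (1 - t^2)` with
#' `t = tanh(bJ)`, and the exact Jensen–Shannon divergence against the
#' uncoupled model.  All stored quantities are recomputable by the
#' enumeration oracle, which the test suite does at load time.
#'
#' @param beta_J Dimensionless coupling (>= 0).
#' @return List of class `"fixture"` with `name`, `model` (a
#'   [spin_model()] at `T = 1` with coupling `beta_J`... realised as a 0/1
#'   graph at temperature `1 / beta_J` when `beta_J > 0`, else a free pair
#'   at `T = 1`) and `exact` quantities.
#' @export
two_spin_fixture <- function(beta_J) {
  stopifnot(beta_J >= 0)
  J <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  model <- if (beta_J > 0) spin_model(as_coupling_matrix(J), 1 / beta_J)
           else spin_model(as_coupling_matrix(matrix(0L, 2, 2)), 1)
  t <- tanh(beta_J)
  js <- if (beta_J > 0) {
    uncoupled <- spin_model(as_coupling_matrix(matrix(0L, 2, 2)), 1 / beta_J)
    exact_f_divergence(model, uncoupled)
  } else 0
  structure(list(name = sprintf("two_spin_bJ_%g", beta_J),
                 model = model,
                 exact = list(pair_correlation = t,
                              means = c(0, 0),
                              C = matrix(c(1, t, t, 1), 2, 2),
                              beta_J_hat = t / (1 - t^2),
                              js_vs_uncoupled = js)),
            class = "fixture")
}

#' Open-chain oracle fixture
#'
#' Ising chain 1-2-...-n with uniform couplings at inverse temperature
#' `beta` and zero field.  The transfer-matrix identity gives exact raw
#' correlations `<s_i s_j> = tanh(beta)^|i - j|`, so indirect correlations
#' are strictly weaker than direct ones and local scores rank the chain
#' perfectly (AUC 1 on exact moments for `beta > 0`).
#'
#' @param n Chain length (2..12; the exact quantities must stay
#'   enumerable).
#' @param beta Inverse temperature (> 0).
#' @return `"fixture"` with the chain `model` and exact `second_moments` /
#'   `C` matrices.
#' @export
chain_fixture <- function(n, beta) {
  stopifnot(n >= 2, n <= 12, beta > 0)
  J <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) J[i, i + 1] <- J[i + 1, i] <- 1L
  model <- spin_model(as_coupling_matrix(J), 1 / beta)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  M <- tanh(beta)^D
  structure(list(name = sprintf("chain_n%d_beta_%g", n, beta),
                 model = model,
                 exact = list(second_moments = M, means = rep(0, n), C = M)),
            class = "fixture")
}

#' Planted common-neighbour motifs
#'
#' Builds a graph as a disjoint union of motifs: each motif has two
#' nonadjacent hub vertices joined through `m` independent common
#' neighbours, so the hub pair sits at graph distance two with exactly `m`
#' shortest paths.  Useful for controlled tests of shortest-path
#' histograms.
#'
#' @param common_neighbors Integer vector; one motif per entry (entries
#'   >= 1).  An empty vector gives the empty graph on `2` vertices.
#' @return A `coupling_matrix` with attribute `motif_pairs`, a data frame
#'   of the planted hub pairs and their path counts.
#' @export
planted_motif_graph <- function(common_neighbors) {
  if (length(common_neighbors) == 0) {
    J <- as_coupling_matrix(matrix(0L, 2, 2))
    attr(J, "motif_pairs") <- data.frame(i = integer(0), j = integer(0),
                                         num_shortest_paths = integer(0))
    return(J)
  }
  stopifnot(all(common_neighbors >= 1))
  n <- sum(common_neighbors + 2)
  J <- matrix(0L, n, n)
  pairs <- list()
  offset <- 0
  for (m in common_neighbors) {
    u <- offset + 1
    v <- offset + 2
    mids <- offset + 2 + seq_len(m)
    for (w in mids) {
      J[u, w] <- J[w, u] <- 1L
      J[v, w] <- J[w, v] <- 1L
    }
    pairs[[length(pairs) + 1]] <- data.frame(i = u, j = v,
                                             num_shortest_paths = m)
    offset <- offset + m + 2
  }
  J <- as_coupling_matrix(J)
  attr(J, "motif_pairs") <- do.call(rbind, pairs)
  J
}
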