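# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Mann-Whitney AUC by explicit pairwise win counting, ties counted 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# Closed-form matrix inverses by the adjugate formula (2x2 and 3x3 only).
adjugate_inverse <- function(M) {
  d <- nrow(M)
  if (d == 2) {
    det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / det
  } else if (d == 3) {
    cof <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      m <- M[-i, -j, drop = FALSE]
      cof[i, j] <- (-1)^(i + j) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
    }
    det <- sum(M[1, ] * cof[1, ])
    t(cof) / det
  } else stop("adjugate oracle handles 2x2/3x3 only")
}

# Graph-distance / shortest-path-count oracle via igraph.
igraph_topology <- function(J) {
  g <- igraph::graph_from_adjacency_matrix(unclass(J), mode = "undirected")
  n <- nrow(J)
  D <- igraph::distances(g)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cnt <- if (is.infinite(D[i, j])) 0
           else length(igraph::all_shortest_paths(g, i, j)$res)
    out[[length(out) + 1]] <- data.frame(i = i, j = j,
                                         graph_distance = D[i, j],
                                         num_shortest_paths = cnt)
  }
  do.call(rbind, out)
}

# Empirical pair second moments <s_i s_j> and their MC standard errors.
moment_check <- function(X, exact_M, n_se = 4) {
  K <- nrow(X)
  M <- crossprod(X) / K
  se <- sqrt(pmax(1 - exact_M^2, 1e-12) / K)
  ok <- abs(M - exact_M) <= n_se * se
  all(ok[upper.tri(ok)])
}

# Exact pair coincidence probabilities <delta(s_i, s_j)> from an
# enumerated Potts distribution.
exact_coincidence <- function(model) {
  d <- exact_distribution(model)
  n <- model$n
  P <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    P[i, j] <- P[j, i] <- sum(d$prob * (d$states[, i] == d$states[, j]))
  P
}
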