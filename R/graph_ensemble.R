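#' Draw a coupling matrix from the Erdős–Rényi ensemble
#'
#' Each unordered vertex pair `i < j` receives an interaction `J_ij = 1`
#' independently with probability `p = mean_degree / n`, giving a uniform
#' ferromagnetic coupling matrix on an Erdős–Rényi random graph with `n`
#' vertices and mean degree `mean_degree` (lambda).  The diagonal is zero
#' and the matrix is symmetric.
#'
#' @param n Number of vertices (integer, at least 2).
#' @param mean_degree Expected vertex degree lambda; the Bernoulli edge
#'   probability is `mean_degree / n`, which must lie in `[0, 1]`.
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return An integer `n x n` symmetric 0/1 matrix of class
#'   `"coupling_matrix"` with attributes `mean_degree` and `seed`.
#' @examples
#' J <- generate_er_couplings(50, 20, seed = 1)
#' sum(J) / 2            # realised edge count
#' @export
generate_er_couplings <- function(n, mean_degree, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2, n == round(n),
            is.numeric(mean_degree), length(mean_degree) == 1L, mean_degree >= 0)
  p <- mean_degree / n
  if (p > 1)
    stop("invalid parameters: mean_degree/n = ", signif(p, 4), " exceeds 1")
  if (!is.null(seed)) set.seed(seed)
  J <- matrix(0L, n, n)
  ut <- upper.tri(J)
  J[ut] <- rbinom(sum(ut), 1L, p)
  J <- J + t(J)
  storage.mode(J) <- "integer"
  structure(J, mean_degree = mean_degree, seed = seed,
            class = c("coupling_matrix", "matrix", "array"))
}

#' Edge list of a coupling matrix
#'
#' @param J Symmetric 0/1 coupling matrix.
#' @return Two-column integer matrix of edges with `i < j` (1-based).
#' @export
edge_list <- function(J) {
  idx <- which(upper.tri(J) & J != 0, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Validate and wrap a symmetric 0/1 matrix as a coupling matrix
#'
#' @param J Symmetric 0/1 matrix with zero diagonal.
#' @param mean_degree,seed Optional provenance attributes.
#' @return A `coupling_matrix`.
#' @export
as_coupling_matrix <- function(J, mean_degree = NA_real_, seed = NULL) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J))
  if (!isTRUE(all.equal(unname(J), unname(t(J)))))
    stop("coupling matrix must be symmetric")
  if (any(diag(J) != 0)) stop("coupling matrix must have zero diagonal")
  if (!all(J %in% c(0, 1))) stop("couplings must be 0/1")
  storage.mode(J) <- "integer"
  structure(J, mean_degree = mean_degree, seed = seed,
            class = c("coupling_matrix", "matrix", "array"))
}

#' @export
print.coupling_matrix <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("coupling_matrix: %d vertices, %d edges (mean degree %.3g)\n",
              n, sum(x) / 2, sum(x) / n))
  invisible(x)
}

#' Randomly perturb a coupling matrix
#'
#' Deletes `n_delete` existing edges and adds `n_add` absent edges, both
#' chosen uniformly without replacement, producing the perturbed matrix `J'`
#' together with a record of the perturbation.  The l1 size
#' `||J' - J||_1 = n_delete + n_add` counts the differing edges (upper
#' triangle).
#'
#' @param J Coupling matrix.
#' @param n_delete,n_add Numbers of edges to delete / add.
#' @param seed Integer RNG seed, independent of the graph seed.
#' @return List with `couplings` (the perturbed `coupling_matrix`) and
#'   `perturbation`: list of `deleted_edges`, `added_edges` (two-column
#'   matrices) and `l1_size`.
#' @export
perturb_graph <- function(J, n_delete, n_add, seed = NULL) {
  stopifnot(n_delete >= 0, n_add >= 0)
  if (!is.null(seed)) set.seed(seed)
  edges <- which(upper.tri(J) & J != 0)
  holes <- which(upper.tri(J) & J == 0)
  if (n_delete > length(edges))
    stop("cannot delete ", n_delete, " edges: graph has only ", length(edges))
  if (n_add > length(holes))
    stop("cannot add ", n_add, " edges: graph has only ", length(holes),
         " vacant pairs")
  del <- if (n_delete > 0) sample(edges, n_delete) else integer(0)
  add <- if (n_add > 0) sample(holes, n_add) else integer(0)
  J2 <- unclass(J)
  flip <- function(M, lin, value) {
    ij <- arrayInd(lin, dim(M))
    M[ij] <- value
    M[ij[, c(2, 1), drop = FALSE]] <- value
    M
  }
  if (length(del)) J2 <- flip(J2, del, 0L)
  if (length(add)) J2 <- flip(J2, add, 1L)
  to_pairs <- function(lin) {
    ij <- arrayInd(lin, dim(J))
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    colnames(ij) <- c("i", "j")
    ij
  }
  list(couplings = as_coupling_matrix(J2, mean_degree = sum(J2) / nrow(J2)),
       perturbation = list(deleted_edges = to_pairs(del),
                           added_edges = to_pairs(add),
                           l1_size = n_delete + n_add))
}

#' Apply (or invert) a recorded graph perturbation
#'
#' Applying a perturbation deletes its `deleted_edges` and adds its
#' `added_edges`; `invert_perturbation()` swaps the two roles, so applying
#' the inverse to the perturbed graph recovers the original.
#'
#' @param J Coupling matrix.
#' @param perturbation A perturbation record from [perturb_graph()].
#' @return A `coupling_matrix`.
#' @export
apply_perturbation <- function(J, perturbation) {
  J2 <- unclass(J)
  d <- perturbation$deleted_edges
  a <- perturbation$added_edges
  if (nrow(d)) {
    if (any(J2[d] != 1)) stop("deleted edges must exist in the source graph")
    J2[d] <- 0L; J2[d[, c(2, 1), drop = FALSE]] <- 0L
  }
  if (nrow(a)) {
    if (any(J2[a] != 0)) stop("added edges must be absent from the source graph")
    J2[a] <- 1L; J2[a[, c(2, 1), drop = FALSE]] <- 1L
  }
  as_coupling_matrix(J2, mean_degree = sum(J2) / nrow(J2))
}

#' @rdname apply_perturbation
#' @export
invert_perturbation <- function(perturbation) {
  list(deleted_edges = perturbation$added_edges,
       added_edges = perturbation$deleted_edges,
       l1_size = perturbation$l1_size)
}

#' Coupling difference and its l1 size
#'
#' @param J_prime,J Coupling matrices of equal dimension.
#' @return List with `delta` (the signed matrix `J' - J`) and `l1_size`,
#'   the number of differing upper-triangle entries.
#' @export
delta_coupling <- function(J_prime, J) {
  stopifnot(all(dim(J_prime) == dim(J)))
  d <- unclass(J_prime) - unclass(J)
  list(delta = d, l1_size = sum(abs(d[upper.tri(d)])))
}

#' Shortest-path topology of every vertex pair
#'
#' Breadth-first layered search from every vertex yields, for each unordered
#' pair, the graph distance and the number of distinct shortest paths.  For
#' pairs at distance two the path count equals the number of common
#' neighbours.  Pairs in different components get distance `Inf` and path
#' count 0.
#'
#' @param J Coupling matrix.
#' @return Data frame with columns `i`, `j`, `label` (1 if the pair is an
#'   edge), `graph_distance`, `num_shortest_paths`.
#' @export
pair_topology <- function(J) {
  n <- nrow(J)
  adj <- lapply(seq_len(n), function(i) which(J[i, ] != 0))
  dist_mat <- matrix(Inf, n, n)
  cnt_mat <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    cnt <- numeric(n)
    dist[s] <- 0
    cnt[s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- d
            cnt[w] <- cnt[w] + cnt[v]
            nxt <- c(nxt, w)
          } else if (dist[w] == d) {
            cnt[w] <- cnt[w] + cnt[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    dist_mat[s, ] <- dist
    cnt_mat[s, ] <- cnt
  }
  ut <- which(upper.tri(dist_mat), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  data.frame(i = ut[, 1], j = ut[, 2],
             label = as.integer(J[ut] != 0),
             graph_distance = dist_mat[ut],
             num_shortest_paths = cnt_mat[ut])
}

#' Fraction of vertex pairs at graph distance greater than two
#'
#' A pair is at distance <= 2 iff it is an edge or has at least one common
#' neighbour, so the fraction follows from the adjacency matrix and its
#' square without a full shortest-path computation.
#'
#' @param J Coupling matrix.
#' @return Fraction of unordered pairs with shortest-path distance > 2
#'   (including disconnected pairs).
#' @export
fraction_distance_gt2 <- function(J) {
  A <- unclass(J)
  A2 <- A %*% A
  ut <- upper.tri(A)
  mean(A[ut] == 0 & A2[ut] == 0)
}

#' Read and write tab-separated edge lists
#'
#' Format: a header comment `# n=<n> lambda=<lambda> seed=<seed>` followed by
#' two tab-separated 1-based integer vertex columns, each edge stored once
#' with `i < j`.
#'
#' @param J Coupling matrix.
#' @param path File path.
#' @return `read_edge_list()` returns a `coupling_matrix`;
#'   `write_edge_list()` invisibly returns `path`.
#' @export
write_edge_list <- function(J, path) {
  el <- edge_list(J)
  seed <- attr(J, "seed")
  header <- sprintf("# n=%d lambda=%s seed=%s", nrow(J),
                    format(attr(J, "mean_degree")),
                    if (is.null(seed)) "NA" else format(seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(el, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("n=([0-9]+) lambda=([0-9.eE+-]+)", header))[[1]]
  if (length(m) < 3) stop("malformed edge-list header: ", header)
  n <- as.integer(m[2])
  lambda <- as.numeric(m[3])
  el <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("i", "j"))
  J <- matrix(0L, n, n)
  if (nrow(el)) {
    ij <- as.matrix(el)
    J[ij] <- 1L
    J[ij[, c(2, 1), drop = FALSE]] <- 1L
  }
  as_coupling_matrix(J, mean_degree = lambda)
}
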