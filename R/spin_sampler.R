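#' Define an Ising or Potts model on a coupling matrix
#'
#' The Hamiltonian is `H = -sum_{i<j} J_ij s_i s_j - sum_i h_i s_i` for
#' Ising spins `s_i` in {-1, +1} (`q = 2`) and
#' `H = -sum_{i<j} J_ij delta(s_i, s_j)` for Potts states `s_i` in 1..q
#' (`q > 2`, Kronecker-delta interaction, zero field).  The Boltzmann
#' distribution is `P(s) = exp(-H/T) / Z`.
#'
#' `q = 2` is treated strictly as the +/-1 Ising model, not as a two-state
#' Potts model (the latter maps to Ising with halved couplings).
#'
#' @param couplings Symmetric coupling matrix (typically 0/1 from
#'   [generate_er_couplings()]).
#' @param temperature Temperature `T > 0`; the inverse temperature is
#'   `beta = 1/T`.
#' @param q Number of single-site states, integer >= 2.
#' @param fields Per-site bias `h_i`; scalar or length-`n` vector.  Must be
#'   zero for Potts models.
#' @return An object of class `"spin_model"`.
#' @export
spin_model <- function(couplings, temperature, q = 2, fields = 0) {
  stopifnot(is.matrix(couplings), nrow(couplings) == ncol(couplings),
            is.numeric(temperature), length(temperature) == 1L, temperature > 0,
            q >= 2, q == round(q))
  n <- nrow(couplings)
  h <- rep_len(as.numeric(fields), n)
  if (q > 2 && any(h != 0)) stop("Potts models support zero field only")
  structure(list(couplings = couplings, temperature = temperature,
                 beta = 1 / temperature, q = as.integer(q), fields = h,
                 n = n),
            class = "spin_model")
}

#' @export
print.spin_model <- function(x, ...) {
  cat(sprintf("spin_model: %s, n = %d, T = %g, %d edges\n",
              if (x$q == 2) "Ising" else sprintf("%d-state Potts", x$q),
              x$n, x$temperature, sum(x$couplings) / 2))
  invisible(x)
}

#' Energy of a spin configuration
#'
#' @param model A [spin_model()].
#' @param configuration Length-`n` vector: values in {-1, +1} (Ising) or
#'   1..q (Potts).
#' @return The Hamiltonian value (a real number).
#' @export
energy <- function(model, configuration) {
  s <- configuration
  stopifnot(length(s) == model$n)
  J <- model$couplings
  if (model$q == 2) {
    if (!all(s %in% c(-1, 1))) stop("Ising configurations take values -1/+1")
    -0.5 * drop(s %*% J %*% s) - sum(model$fields * s)
  } else {
    if (!all(s %in% seq_len(model$q))) stop("Potts states must lie in 1..q")
    el <- edge_list(J)
    -sum(J[el] * (s[el[, 1]] == s[el[, 2]]))
  }
}

#' Exhaustively enumerate the Boltzmann distribution
#'
#' Enumeration oracle for small systems: refuses state spaces larger than
#' 2^20 configurations.  Used throughout the test suite to validate the
#' Monte Carlo samplers and moment estimators.
#'
#' @param model A [spin_model()].
#' @return List of class `"exact_distribution"` with `states`
#'   (`q^n x n` matrix), `prob` (normalised probabilities) and `log_Z`.
#' @export
exact_distribution <- function(model) {
  n <- model$n
  q <- model$q
  if (q^n > 2^20)
    stop("state space q^n = ", q^n, " exceeds the enumeration cap 2^20; ",
         "exact_distribution is a test oracle, not a production sampler")
  vals <- if (q == 2) c(-1L, 1L) else seq_len(q)
  S <- as.matrix(expand.grid(rep(list(vals), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(S) <- NULL
  J <- unclass(model$couplings)
  if (q == 2) {
    E <- -0.5 * rowSums((S %*% J) * S) - drop(S %*% model$fields)
  } else {
    el <- edge_list(J)
    E <- numeric(nrow(S))
    for (e in seq_len(nrow(el))) {
      w <- J[el[e, 1], el[e, 2]]
      E <- E - w * (S[, el[e, 1]] == S[, el[e, 2]])
    }
  }
  logw <- -model$beta * E
  mx <- max(logw)
  w <- exp(logw - mx)
  Z <- sum(w)
  structure(list(states = S, prob = w / Z, log_Z = mx + log(Z),
                 model = model),
            class = "exact_distribution")
}

new_sample_set <- function(X, model, sampler, seed, extra = list()) {
  storage.mode(X) <- "integer"
  attr(X, "q") <- model$q
  attr(X, "temperature") <- model$temperature
  attr(X, "n") <- ncol(X)
  attr(X, "sampler") <- sampler
  attr(X, "seed") <- seed
  attr(X, "graph_checksum") <- sum(model$couplings * seq_along(model$couplings))
  for (nm in names(extra)) attr(X, nm) <- extra[[nm]]
  class(X) <- c("sample_set", "matrix", "array")
  X
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: K = %d configurations of %d spins (q = %d, T = %g, sampler = %s)\n",
              nrow(x), ncol(x), attr(x, "q"), attr(x, "temperature"),
              attr(x, "sampler")))
  invisible(x)
}

#' Keep the first k configurations of a sample set
#'
#' Plain matrix subsetting drops provenance attributes; this keeps them.
#'
#' @param samples A `sample_set`.
#' @param k Number of configurations to retain (or a row index vector).
#' @return A `sample_set`.
#' @export
subset_samples <- function(samples, k) {
  idx <- if (length(k) == 1L) seq_len(k) else k
  out <- unclass(samples)[idx, , drop = FALSE]
  for (nm in setdiff(names(attributes(samples)), c("dim", "dimnames")))
    attr(out, nm) <- attr(samples, nm)
  class(out) <- class(samples)
  out
}

#' Exact Boltzmann sampling by monotone coupling from the past
#'
#' Draws `K` independent exact samples from the Ising Boltzmann distribution
#' using the Propp–Wilson construction: heat-bath chains started from the
#' all-up and all-down configurations are run from successively doubled
#' times in the past with shared, reused randomness; their coalescence at
#' time zero certifies that the returned state is an unbiased draw from the
#' stationary distribution.  Monotonicity requires ferromagnetic couplings
#' (`J >= 0`); fields of either sign are allowed.
#'
#' Coalescence times grow sharply below the critical temperature for large
#' systems (the chain must cross the free-energy barrier between the two
#' ordered modes); use [sample_gibbs()] there.
#'
#' @param model A [spin_model()] with `q = 2` and nonnegative couplings.
#' @param K Number of independent samples.
#' @param seed Integer RNG seed.
#' @param max_sweeps Cap on the epoch length, in sweeps (default `2^20`);
#'   non-coalescence beyond it raises a diagnostic error.
#' @param check_sandwich If `TRUE`, verify at every update that the
#'   all-down chain stays pointwise below the all-up chain; the result is
#'   stored in attribute `sandwich_ok`.
#' @return A `sample_set` (`K x n` matrix of -1/+1) with provenance
#'   attributes, including `updates_used` per draw.
#' @export
sample_ising_exact <- function(model, K, seed = NULL, max_sweeps = 2^20,
                               check_sandwich = FALSE) {
  stopifnot(K >= 1)
  if (model$q != 2) stop("coupling from the past is implemented for Ising (q = 2) only")
  if (any(model$couplings < 0))
    stop("negative couplings break the monotone coupling; ferromagnetic models only")
  if (!is.null(seed)) set.seed(seed)
  el <- edge_list(model$couplings)
  res <- cpp_cftp_ising(el, model$n, model$beta, model$fields, as.integer(K),
                        max_sweeps * model$n, check_sandwich)
  new_sample_set(res$samples, model, "cftp", seed,
                 extra = list(updates_used = res$updates_used,
                              sandwich_ok = res$sandwich_ok))
}

#' Gibbs (heat-bath) sampling with symmetry relabelling
#'
#' Random-scan single-site heat-bath updates; after burn-in every
#' `thinning`-th sweep's configuration is retained.  With zero fields the
#' Boltzmann distribution is invariant under a global relabelling of the
#' states (Ising: global flip; Potts: permutation of the q labels), and each
#' retained configuration is followed by a uniformly random relabelling of
#' the chain, which restores ergodicity across symmetry-broken modes at low
#' temperature.
#'
#' @param model A [spin_model()].
#' @param K Number of retained configurations.
#' @param seed Integer RNG seed.
#' @param burn_in Burn-in length in sweeps (default 1000).
#' @param thinning Sweeps between retained configurations (default 10).
#' @param relabel Apply the random global relabelling (default `TRUE`;
#'   forced off when any field is nonzero).
#' @return A `sample_set` (`K x n` matrix).
#' @export
sample_gibbs <- function(model, K, seed = NULL, burn_in = 1000, thinning = 10,
                         relabel = TRUE) {
  stopifnot(K >= 1, burn_in >= 1, thinning >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (relabel && any(model$fields != 0)) relabel <- FALSE
  el <- edge_list(model$couplings)
  X <- if (model$q == 2) {
    cpp_gibbs_ising(el, model$n, model$beta, model$fields, as.integer(K),
                    as.integer(burn_in), as.integer(thinning), relabel)
  } else {
    cpp_gibbs_potts(el, model$n, model$q, model$beta, as.integer(K),
                    as.integer(burn_in), as.integer(thinning), relabel)
  }
  new_sample_set(X, model, "gibbs", seed,
                 extra = list(burn_in = burn_in, thinning = thinning,
                              relabel = relabel))
}

#' Read and write sample sets as tab-separated text
#'
#' One configuration per row; header comments record n, q, T, K, sampler,
#' seed and a graph checksum.
#'
#' @param samples A `sample_set`.
#' @param path File path.
#' @return `read_sample_set()` returns a `sample_set`;
#'   `write_sample_set()` invisibly returns `path`.
#' @export
write_sample_set <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in c("n", "q", "temperature", "sampler", "seed", "graph_checksum"))
    writeLines(sprintf("# %s=%s", nm,
                       if (is.null(attr(samples, nm))) "NA"
                       else format(attr(samples, nm))), con)
  writeLines(sprintf("# K=%d", nrow(samples)), con)
  write.table(unclass(samples), con, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- regmatches(hdr, regexec(paste0("^# ", key, "=(.*)$"), hdr))
    v <- unlist(lapply(m, function(x) if (length(x) == 2) x[2] else NULL))
    if (length(v)) v[1] else NA
  }
  X <- as.matrix(read.table(path, sep = "\t", comment.char = "#"))
  dimnames(X) <- NULL
  storage.mode(X) <- "integer"
  attr(X, "q") <- as.integer(get("q"))
  attr(X, "temperature") <- as.numeric(get("temperature"))
  attr(X, "n") <- ncol(X)
  attr(X, "sampler") <- get("sampler")
  class(X) <- c("sample_set", "matrix", "array")
  X
}
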