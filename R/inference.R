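#' Empirical moments of a sample set
#'
#' Plug-in (denominator K) estimates of single-site means and connected
#' correlations.  Ising: means `<s_i>` and the `n x n` matrices of raw
#' second moments `<s_i s_j>` and connected correlations
#' `C_ij = <s_i s_j> - <s_i><s_j>`.  Potts: sites are one-hot encoded with
#' one reference state dropped per site (`q - 1` components), giving an
#' `n(q-1) x n(q-1)` connected correlation matrix; the full `n x q` state
#' frequencies are kept alongside.
#'
#' @param samples A `sample_set` (or plain matrix of -1/+1 or 1..q values).
#' @param drop_state Potts reference state to drop (default `q`).
#' @return An object of class `"moment_estimates"`.
#' @export
estimate_moments <- function(samples, drop_state = NULL) {
  X <- unclass(samples)
  K <- nrow(X)
  n <- ncol(X)
  stopifnot(K >= 2)
  q <- attr(samples, "q")
  if (is.null(q)) q <- if (all(X %in% c(-1L, 1L))) 2L else max(X)
  if (q == 2 && all(X %in% c(-1L, 1L))) {
    m <- colMeans(X)
    M <- crossprod(X) / K
    C <- M - tcrossprod(m)
    structure(list(q = 2L, n = n, K = K, means = m, second_moments = M,
                   connected_correlations = C),
              class = "moment_estimates")
  } else {
    if (is.null(drop_state)) drop_state <- q
    kept <- setdiff(seq_len(q), drop_state)
    H <- matrix(0, K, n * (q - 1))
    for (a in seq_along(kept))
      H[, (seq_len(n) - 1) * (q - 1) + a] <- (X == kept[a])
    mu <- colMeans(H)
    C <- crossprod(H) / K - tcrossprod(mu)
    freq <- vapply(seq_len(q), function(a) colMeans(X == a), numeric(n))
    structure(list(q = as.integer(q), n = n, K = K,
                   means = matrix(mu, n, q - 1, byrow = TRUE),
                   freq = freq, kept_states = kept,
                   drop_state = drop_state,
                   connected_correlations = C),
              class = "moment_estimates")
  }
}

#' Exact moments from the enumeration oracle
#'
#' Computes the same `moment_estimates` structure as [estimate_moments()]
#' but from the exhaustive Boltzmann distribution of [exact_distribution()]
#' (`K` is recorded as `Inf`).
#'
#' @param model A [spin_model()] small enough to enumerate.
#' @param drop_state Potts reference state to drop (default `q`).
#' @return A `moment_estimates` object.
#' @export
exact_moments <- function(model, drop_state = NULL) {
  dist <- exact_distribution(model)
  S <- dist$states
  p <- dist$prob
  n <- model$n
  q <- model$q
  if (q == 2) {
    m <- drop(p %*% S)
    M <- crossprod(S, S * p)
    C <- M - tcrossprod(m)
    structure(list(q = 2L, n = n, K = Inf, means = m, second_moments = M,
                   connected_correlations = C),
              class = "moment_estimates")
  } else {
    if (is.null(drop_state)) drop_state <- q
    kept <- setdiff(seq_len(q), drop_state)
    H <- matrix(0, nrow(S), n * (q - 1))
    for (a in seq_along(kept))
      H[, (seq_len(n) - 1) * (q - 1) + a] <- (S == kept[a])
    mu <- drop(p %*% H)
    C <- crossprod(H, H * p) - tcrossprod(mu)
    freq <- vapply(seq_len(q), function(a) drop(p %*% (S == a)), numeric(n))
    structure(list(q = as.integer(q), n = n, K = Inf,
                   means = matrix(mu, n, q - 1, byrow = TRUE),
                   freq = freq, kept_states = kept, drop_state = drop_state,
                   connected_correlations = C),
              class = "moment_estimates")
  }
}

#' @export
print.moment_estimates <- function(x, ...) {
  cat(sprintf("moment_estimates: n = %d, q = %d, K = %s\n", x$n, x$q,
              format(x$K)))
  invisible(x)
}

potts_block_index <- function(i, q) ((i - 1) * (q - 1) + 1):((i - 1) * (q - 1) + (q - 1))

# complete a dropped-state (q-1)x(q-1) covariance block to the full q x q
# block; one-hot indicators sum to 1 per site, so rows/columns of the full
# block sum to zero.
complete_cov_block <- function(B) {
  qm <- nrow(B)
  full <- matrix(0, qm + 1, qm + 1)
  full[1:qm, 1:qm] <- B
  full[qm + 1, 1:qm] <- -colSums(B)
  full[1:qm, qm + 1] <- -rowSums(B)
  full[qm + 1, qm + 1] <- sum(B)
  full
}

#' Naive mean-field inversion of the connected correlation matrix
#'
#' The mean-field direct-coupling estimator: `beta * Jhat_ij = -(C^-1)_ij`
#' for `i < j`.  A ridge term `ridge * I` is added before inversion; the
#' default `1e-8 * trace(C) / dim` keeps the estimator essentially
#' unregularised while making rank-deficient corner cases reproducible.
#' With `ridge = 0` a singular matrix raises an error naming the rank
#' deficiency.  For Potts data the inverse is taken on the dropped one-hot
#' encoding and couplings live in per-pair `(q-1) x (q-1)` blocks
#' (see [coupling_block()]).
#'
#' @param moments A `moment_estimates` object.
#' @param temperature Temperature used to de-dimensionalise: `Jhat = T *
#'   beta_Jhat` is reported when given.
#' @param ridge Ridge strength; `NULL` for the default above.
#' @return An object of class `"inferred_couplings"`: fields `beta_J`
#'   (Ising `n x n`, zero diagonal), `J` (if `temperature` given),
#'   `precision` (the negated inverse, Potts), `ridge`, `temperature`.
#' @export
mean_field_inversion <- function(moments, temperature = NULL, ridge = NULL) {
  C <- moments$connected_correlations
  d <- nrow(C)
  if (is.null(ridge)) ridge <- 1e-8 * sum(diag(C)) / d
  if (ridge == 0) {
    r <- qr(C)$rank
    if (r < d)
      stop("connected correlation matrix is singular (rank ", r, " of ", d,
           "); supply ridge > 0 or more samples")
    Cinv <- solve(C)
  } else {
    Cinv <- solve(C + diag(ridge, d))
  }
  out <- list(q = moments$q, n = moments$n, ridge = ridge,
              temperature = temperature)
  if (moments$q == 2) {
    B <- -Cinv
    diag(B) <- 0
    out$beta_J <- (B + t(B)) / 2
    if (!is.null(temperature)) out$J <- temperature * out$beta_J
  } else {
    out$precision <- Cinv
    out$drop_state <- moments$drop_state
    out$kept_states <- moments$kept_states
  }
  structure(out, class = "inferred_couplings")
}

#' @export
print.inferred_couplings <- function(x, ...) {
  cat(sprintf("inferred_couplings: n = %d, q = %d, ridge = %g\n",
              x$n, x$q, x$ridge))
  invisible(x)
}

#' Extract a Potts coupling block
#'
#' Returns the inferred `q x q` coupling block `beta * Jhat_ij(a, b)` for a
#' pair, either in the reference gauge (dropped state's row/column zero) or
#' after zero-sum gauge projection (rows and columns average to zero),
#' which is invariant to the choice of dropped state.
#'
#' @param inferred Potts `inferred_couplings`.
#' @param i,j Vertex pair.
#' @param gauge `"zero_sum"` (default) or `"reference"`.
#' @return A `q x q` matrix.
#' @export
coupling_block <- function(inferred, i, j, gauge = c("zero_sum", "reference")) {
  gauge <- match.arg(gauge)
  stopifnot(inferred$q > 2)
  q <- inferred$q
  B <- -inferred$precision[potts_block_index(i, q), potts_block_index(j, q)]
  full <- matrix(0, q, q)
  full[inferred$kept_states, inferred$kept_states] <- B
  if (gauge == "zero_sum") {
    rm <- rowMeans(full); cm <- colMeans(full); tm <- mean(full)
    full <- full - outer(rm, rep(1, q)) - outer(rep(1, q), cm) + tm
  }
  full
}

pair_grid <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

attach_labels <- function(df, truth) {
  if (!is.null(truth)) df$label <- as.integer(truth[cbind(df$i, df$j)] != 0)
  else df$label <- NA_integer_
  df
}

#' Local (pairwise-statistics) interaction scores
#'
#' Ising: the raw empirical pair correlation `<s_i s_j>`.  Potts: the
#' Frobenius norm of the pair's full `q x q` connected-correlation block
#' (completed from the dropped encoding; invariant to the dropped state).
#'
#' @param moments A `moment_estimates` object.
#' @param truth Optional ground-truth `coupling_matrix` supplying labels.
#' @return Data frame (`i`, `j`, `score`, `label`) with attribute
#'   `method = "local"`.
#' @export
local_scores <- function(moments, truth = NULL) {
  pg <- pair_grid(moments$n)
  if (moments$q == 2) {
    score <- moments$second_moments[pg]
  } else {
    q <- moments$q
    C <- moments$connected_correlations
    score <- vapply(seq_len(nrow(pg)), function(k) {
      B <- C[potts_block_index(pg[k, 1], q), potts_block_index(pg[k, 2], q)]
      sqrt(sum(complete_cov_block(B)^2))
    }, numeric(1))
  }
  df <- attach_labels(data.frame(i = pg[, 1], j = pg[, 2], score = score),
                      truth)
  attr(df, "method") <- "local"
  df
}

# vectorised Newton solver for the two-spin field-matching problem:
# given beta*Jhat and target means (mi, mj), find (hi, hj) such that the
# two-spin model exp(bJ s1 s2 + hi s1 + hj s2)/Z has those marginals.
# Returns the matched fields and the model's pair correlation.
match_fields <- function(bJ, mi, mj, tol = 1e-10, max_iter = 1000) {
  stopifnot(length(mi) == length(bJ), length(mj) == length(bJ))
  clamp <- function(x) pmin(pmax(x, -1 + 1e-12), 1 - 1e-12)
  hi <- atanh(clamp(mi))
  hj <- atanh(clamp(mj))
  two_spin <- function(hi, hj) {
    a <- cbind(bJ + hi + hj, -bJ + hi - hj, -bJ - hi + hj, bJ - hi - hj)
    mx <- apply(a, 1, max)
    w <- exp(a - mx)
    Z <- rowSums(w)
    list(mi = (w[, 1] + w[, 2] - w[, 3] - w[, 4]) / Z,
         mj = (w[, 1] - w[, 2] + w[, 3] - w[, 4]) / Z,
         corr = (w[, 1] - w[, 2] - w[, 3] + w[, 4]) / Z)
  }
  active <- rep(TRUE, length(bJ))
  st <- two_spin(hi, hj)
  for (iter in seq_len(max_iter)) {
    ri <- mi - st$mi
    rj <- mj - st$mj
    active <- pmax(abs(ri), abs(rj)) > tol
    if (!any(active)) break
    vi <- 1 - st$mi^2
    vj <- 1 - st$mj^2
    cv <- st$corr - st$mi * st$mj
    det <- pmax(vi * vj - cv^2, 1e-300)
    si <- (vj * ri - cv * rj) / det
    sj <- (vi * rj - cv * ri) / det
    # damp long steps; Newton is quadratic once close
    sc <- pmax(1, pmax(abs(si), abs(sj)) / 2)
    hi <- ifelse(active, hi + si / sc, hi)
    hj <- ifelse(active, hj + sj / sc, hj)
    st <- two_spin(hi, hj)
  }
  list(h_i = hi, h_j = hj, corr = st$corr,
       converged = !any(active),
       residual = max(abs(c(mi - st$mi, mj - st$mj))))
}

#' Direct pairwise distribution of an inferred coupling
#'
#' Builds the two-spin model
#' `P_dir(s_i, s_j) = exp(bJ s_i s_j + h_i s_i + h_j s_j) / Z` whose fields
#' are chosen so that its marginals reproduce the empirical single-spin
#' means to 1e-8 (damped Newton on the two marginal residuals).  Its pair
#' correlation `<s_i s_j>_dir` is the global interaction score.
#'
#' @param coupling Inferred `beta * Jhat` for the pair.
#' @param empirical_means Length-2 vector `(m_i, m_j)`, each in `(-1, 1)`.
#'   Boundary values `|m| = 1` are degenerate: the score is forced to
#'   `m_i * m_j` with a warning.
#' @param tol Matching tolerance (default 1e-8 per the contract; the solver
#'   typically reaches 1e-12).
#' @return List with `coupling`, `matching_fields`, `direct_correlation`.
#' @export
direct_pair_model <- function(coupling, empirical_means, tol = 1e-8) {
  m <- empirical_means
  stopifnot(length(m) == 2, all(abs(m) <= 1))
  if (any(abs(m) == 1)) {
    warning("degenerate marginal |m| = 1: direct correlation forced to m_i * m_j")
    return(list(coupling = coupling,
                matching_fields = c(sign(m[1]) * Inf, sign(m[2]) * Inf),
                direct_correlation = m[1] * m[2]))
  }
  fit <- match_fields(coupling, m[1], m[2], tol = min(tol, 1e-10))
  if (fit$residual > tol)
    stop("field matching failed to reach tolerance: residual ", fit$residual)
  list(coupling = coupling,
       matching_fields = c(fit$h_i, fit$h_j),
       direct_correlation = fit$corr)
}

#' Global (direct-coupling) interaction scores
#'
#' Ising: the direct correlation `<s_i s_j>_dir` of each pair's
#' [direct_pair_model()], built from the mean-field inverted coupling and
#' marginal-matched fields.  Potts: the Frobenius norm of the zero-sum
#' gauge coupling block (no average-product correction).
#'
#' @param inferred An `inferred_couplings` object.
#' @param moments The `moment_estimates` the inversion was computed from.
#' @param truth Optional ground-truth `coupling_matrix` supplying labels.
#' @return Data frame (`i`, `j`, `score`, `label`) with attribute
#'   `method = "global"`.
#' @export
global_scores <- function(inferred, moments, truth = NULL) {
  pg <- pair_grid(inferred$n)
  if (inferred$q == 2) {
    m <- moments$means
    mi <- m[pg[, 1]]
    mj <- m[pg[, 2]]
    bJ <- inferred$beta_J[pg]
    degen <- abs(mi) >= 1 - 1e-15 | abs(mj) >= 1 - 1e-15
    score <- numeric(nrow(pg))
    if (any(!degen)) {
      fit <- match_fields(bJ[!degen], mi[!degen], mj[!degen])
      score[!degen] <- fit$corr
    }
    if (any(degen)) {
      warning(sum(degen), " pair(s) with degenerate marginals |m| = 1: ",
              "direct correlation forced to m_i * m_j")
      score[degen] <- mi[degen] * mj[degen]
    }
  } else {
    score <- vapply(seq_len(nrow(pg)), function(k) {
      sqrt(sum(coupling_block(inferred, pg[k, 1], pg[k, 2])^2))
    }, numeric(1))
  }
  df <- attach_labels(data.frame(i = pg[, 1], j = pg[, 2], score = score),
                      truth)
  attr(df, "method") <- "global"
  df
}

#' Write a scores table
#'
#' Tab-separated columns `i`, `j`, `label`, `local_score`, `global_score`,
#' `beta_J_hat`.
#'
#' @param local,global Score data frames from [local_scores()] /
#'   [global_scores()] on the same pairs.
#' @param inferred The `inferred_couplings` (for the `beta_J_hat` column;
#'   Ising only, `NA` otherwise).
#' @param path Output file.
#' @export
write_scores_table <- function(local, global, inferred, path) {
  stopifnot(all(local$i == global$i), all(local$j == global$j))
  bJ <- if (inferred$q == 2) inferred$beta_J[cbind(local$i, local$j)] else NA
  out <- data.frame(i = local$i, j = local$j, label = local$label,
                    local_score = local$score, global_score = global$score,
                    beta_J_hat = bJ)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
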