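#' The Jensen–Shannon f-divergence generator
#'
#' `f(t) = (t + 1) * log2(2 / (t + 1)) + t * log2(t)`, continuous at
#' `t = 0` (where `t log2 t -> 0`, so `f(0) = 1`), convex with `f(1) = 0`
#' and `f''(1) = 1 / (2 ln 2)`.  This generator yields exactly twice the
#' conventional Jensen–Shannon divergence, in bits, so values lie in
#' `[0, 2]`; it is implemented as stated, with no rescaling.
#'
#' @return List of class `"f_generator"` with fields `name`, `f`
#'   (vectorised evaluation) and `f_second_deriv`.
#' @export
js_generator <- function() {
  f <- function(t) {
    if (any(t < 0)) stop("f-divergence generators are defined on t >= 0")
    tl <- ifelse(t > 0, t * log2(t), 0)
    (t + 1) * log2(2 / (t + 1)) + tl
  }
  structure(list(name = "jensen-shannon", f = f,
                 f_second_deriv = 1 / (2 * log(2))),
            class = "f_generator")
}

#' Exact f-divergence between two enumerable models
#'
#' Enumeration oracle: `D_f(P || Q) = sum_s Q(s) f(P(s) / Q(s))` with
#' `P` the model on the perturbed graph and `Q` the reference model.  Both
#' models must share the state space.
#'
#' @param model_prime,model [spin_model()]s on graphs `J'` and `J`.
#' @param f An `f_generator` (default Jensen–Shannon).
#' @return The divergence value.
#' @export
exact_f_divergence <- function(model_prime, model, f = js_generator()) {
  stopifnot(model_prime$n == model$n, model_prime$q == model$q)
  P <- exact_distribution(model_prime)$prob
  Q <- exact_distribution(model)$prob
  sum(Q * f$f(P / Q))
}

quad_form_delta <- function(X, delta, beta) {
  ut <- which(upper.tri(delta) & delta != 0, arr.ind = TRUE)
  v <- numeric(nrow(X))
  for (e in seq_len(nrow(ut))) {
    w <- delta[ut[e, 1], ut[e, 2]]
    v <- v + w * X[, ut[e, 1]] * X[, ut[e, 2]]
  }
  beta * v
}

#' Importance-sampling estimate of the f-divergence between Ising models
#'
#' Estimates `D_f(J', J)` from samples of the reference model `H_J` alone:
#' the likelihood ratio `P_{J'}(s) / P_J(s)` equals
#' `exp(beta * sum_{i<j} dJ_ij s_i s_j)` divided by the partition-function
#' ratio, which is itself estimated as the normaliser-sample average of the
#' same exponential.  The outer average applies the generator `f` to the
#' per-sample ratio; its delete-one jackknife standard error is reported.
#' All exponentials are handled in log space.
#'
#' By default one sample set is split into disjoint halves for the outer
#' and normaliser averages, avoiding reuse bias; pass `reuse = TRUE` (or
#' the same object twice) for the naive same-sample estimator.
#'
#' @param samples_primary `sample_set` drawn from the reference model `H_J`
#'   (outer average).
#' @param samples_normalizer Second `sample_set` from the same model for
#'   the partition-function ratio; `NULL` splits `samples_primary` in half.
#' @param delta_J Signed difference matrix `J' - J`.
#' @param beta Inverse temperature used for both models.
#' @param f An `f_generator` (default Jensen–Shannon).
#' @param reuse If `TRUE` and no normaliser set is given, use the full
#'   primary set for both averages.
#' @return List of class `"divergence_estimate"`: `value`,
#'   `standard_error`, `sample_size` (outer), `l1_size`, `ess_inner`.
#' @export
estimate_f_divergence <- function(samples_primary, samples_normalizer = NULL,
                                  delta_J, beta, f = js_generator(),
                                  reuse = FALSE) {
  X <- unclass(samples_primary)
  stopifnot(ncol(X) == nrow(delta_J), nrow(delta_J) == ncol(delta_J))
  if (is.null(samples_normalizer)) {
    if (reuse) {
      X1 <- X; X0 <- X
    } else {
      K <- nrow(X)
      X1 <- X[seq_len(K %/% 2), , drop = FALSE]
      X0 <- X[(K %/% 2 + 1):K, , drop = FALSE]
    }
  } else {
    X1 <- X
    X0 <- unclass(samples_normalizer)
    stopifnot(ncol(X0) == ncol(X))
  }
  s1 <- quad_form_delta(X1, delta_J, beta)
  s0 <- quad_form_delta(X0, delta_J, beta)
  mx <- max(s0)
  w <- exp(s0 - mx)
  log_ratio_Z <- mx + log(mean(w))   # log <exp(beta dJ s s)>_J
  ess <- sum(w)^2 / sum(w^2)
  if (ess < 100)
    warning("effective sample size of the normaliser average is ",
            round(ess, 1), "; the divergence estimate may be unreliable")
  fv <- f$f(exp(s1 - log_ratio_Z))
  K1 <- length(fv)
  se <- sqrt(sum((fv - mean(fv))^2) / (K1 * (K1 - 1)))  # delete-one jackknife
  structure(list(value = mean(fv), standard_error = se,
                 sample_size = K1,
                 l1_size = sum(abs(delta_J[upper.tri(delta_J)])),
                 ess_inner = ess),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("divergence_estimate: %.5f +/- %.5f (K = %d, ||dJ||_1 = %d, inner ESS = %.0f)\n",
              x$value, x$standard_error, x$sample_size, x$l1_size,
              x$ess_inner))
  invisible(x)
}

#' Divergence sweep over perturbations and temperatures
#'
#' For every (perturbation, temperature) combination: draw fresh samples
#' from the reference model `H_J`, estimate the f-divergence to the
#' perturbed model, and tabulate it alongside the mean-field prediction.
#' Rows group naturally by `l1_size`.
#'
#' @param J Reference `coupling_matrix`.
#' @param perturbations List of perturbation records from [perturb_graph()]
#'   (fields `deleted_edges`, `added_edges`, `l1_size`).
#' @param temperatures Absolute temperatures to sweep.
#' @param K Total sample budget per estimate (split in halves).
#' @param seed RNG seed; the whole sweep is deterministic given it.
#' @param f An `f_generator`.
#' @param sampler `"gibbs"` (default) or `"cftp"`.
#' @param burn_in,thinning Gibbs settings.
#' @return Data frame with columns `temperature`, `t_over_tc`, `l1_size`,
#'   `estimate`, `stderr`, `mean_field_value`, `ess_inner`.
#' @export
divergence_sweep <- function(J, perturbations, temperatures, K, seed = NULL,
                             f = js_generator(), sampler = c("gibbs", "cftp"),
                             burn_in = 1000, thinning = 10) {
  sampler <- match.arg(sampler)
  if (!is.null(seed)) set.seed(seed)
  lambda <- attr(J, "mean_degree")
  if (is.null(lambda) || is.na(lambda)) lambda <- sum(J) / nrow(J)
  tc <- critical_temperature(lambda, 2)
  rows <- list()
  for (p in perturbations) {
    J2 <- apply_perturbation(J, p)
    dJ <- delta_coupling(J2, J)$delta
    for (T in temperatures) {
      model <- spin_model(J, T)
      samples <- if (sampler == "cftp") sample_ising_exact(model, K)
                 else sample_gibbs(model, K, burn_in = burn_in,
                                   thinning = thinning)
      est <- estimate_f_divergence(samples, NULL, dJ, 1 / T, f)
      rows[[length(rows) + 1]] <- data.frame(
        temperature = T, t_over_tc = T / tc, l1_size = est$l1_size,
        estimate = est$value, stderr = est$standard_error,
        mean_field_value = mf_f_divergence(T, lambda, est$l1_size,
                                           f$f_second_deriv),
        ess_inner = est$ess_inner)
    }
  }
  do.call(rbind, rows)
}
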