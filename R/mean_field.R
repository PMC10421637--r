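#' Mean-field Ising order parameter
#'
#' Solves the self-consistency equation `Delta = tanh(lambda * Delta / T)`
#' for the largest nonnegative root by bracketed root-finding (absolute
#' tolerance 1e-10 or better).  For `T >= lambda` the only root is 0.
#'
#' @param temperature Temperature(s) `T > 0` (vectorised).
#' @param mean_degree Mean degree lambda (> 0); the mean-field critical
#'   temperature is `Tc = lambda`.
#' @return Order parameter(s) in `[0, 1]`.
#' @export
ising_order_parameter <- function(temperature, mean_degree) {
  stopifnot(all(temperature > 0), mean_degree > 0)
  vapply(temperature, function(T) {
    if (T >= mean_degree) return(0)
    uniroot(function(d) d - tanh(mean_degree * d / T),
            interval = c(1e-12, 1), tol = 1e-12)$root
  }, numeric(1))
}

# mean-field Potts free energy per site at order parameter s in [0, 1];
# single-site marginal: (1 + (q-1) s)/q for the preferred state, (1 - s)/q
# for the rest.
potts_free_energy <- function(s, temperature, mean_degree, q) {
  p1 <- (1 + (q - 1) * s) / q
  po <- (1 - s) / q
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  entropy <- -(xlogx(p1) + (q - 1) * xlogx(po))
  -(mean_degree / 2) * (1 + (q - 1) * s^2) / q - temperature * entropy
}

#' Mean-field Potts order parameter
#'
#' Solves the standard mean-field self-consistency
#' `s = (exp(beta*lambda*s) - 1) / (exp(beta*lambda*s) + q - 1)` and selects
#' the stable branch by global minimisation of the mean-field free energy.
#' For `q > 2` the transition is first order: the curve jumps by
#' `(q - 2)/(q - 1)` at the transition temperature.  The order parameter
#' uses the `(q * p_max - 1)/(q - 1)` normalisation.
#'
#' Note the `q = 2` branch of this self-consistency describes the two-state
#' Potts model, which equals the +/-1 Ising model with halved couplings:
#' `potts_order_parameter(T, lambda, 2)` equals
#' `ising_order_parameter(2 * T, lambda)`.
#'
#' @inheritParams ising_order_parameter
#' @param q Number of states (integer >= 2).
#' @return Order parameter(s) in `[0, 1]`.
#' @export
potts_order_parameter <- function(temperature, mean_degree, q) {
  stopifnot(all(temperature > 0), mean_degree > 0, q >= 2)
  vapply(temperature, function(T) {
    b <- 1 / T
    g <- function(s) s - (exp(b * mean_degree * s) - 1) /
      (exp(b * mean_degree * s) + q - 1)
    # locate nontrivial roots by sign-change scan on (0, 1]
    grid <- seq(1e-6, 1 - 1e-12, length.out = 2000)
    gv <- g(grid)
    roots <- 0
    sgn <- sign(gv)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (k in idx) {
      r <- uniroot(g, c(grid[k], grid[k + 1]), tol = 1e-12)$root
      roots <- c(roots, r)
    }
    fe <- potts_free_energy(roots, T, mean_degree, q)
    # global minimum; on an exact tie prefer the ordered (larger) root
    best <- which(fe <= min(fe) + 1e-12)
    max(roots[best])
  }, numeric(1))
}

#' Critical temperature of the mean-field transition
#'
#' Ising (`q = 2`): `Tc = lambda`.  Potts (`q > 2`): the first-order
#' transition temperature where the ordered free-energy minimum crosses the
#' disordered one, located numerically by bisection (it agrees with the
#' closed form `lambda * (q - 2) / (2 * (q - 1) * log(q - 1))`).
#'
#' @inheritParams potts_order_parameter
#' @return The critical temperature.
#' @export
critical_temperature <- function(mean_degree, q = 2) {
  stopifnot(mean_degree > 0, q >= 2)
  if (q == 2) return(mean_degree)
  crosses <- function(T) potts_order_parameter(T, mean_degree, q) > 1e-6
  lo <- mean_degree / q          # spinodal of the disordered solution
  hi <- mean_degree              # safely disordered
  stopifnot(crosses(lo), !crosses(hi))
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    if (crosses(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean-field f-divergence between models on perturbed graphs
#'
#' Small-coupling mean-field expansion of the f-divergence between Ising
#' models whose 0/1 coupling matrices differ in `l1_size` edges:
#' `D_mf = (1/2) * f''(1) * l1_size * (1 - Delta(T)^4) / T^2`,
#' with `Delta(T)` the mean-field Ising order parameter.  Above `Tc` the
#' curve decays exactly as `T^-2`; the competition between thermal noise
#' and macroscopic order places its maximum at `T/Tc ~ 0.83`.
#'
#' @inheritParams ising_order_parameter
#' @param l1_size Number of differing edges `||J' - J||_1`.
#' @param f_second_deriv `f''(1)` of the divergence generator; defaults to
#'   the Jensen–Shannon value `1 / (2 * log(2))` (see [js_generator()]).
#' @return Mean-field divergence value(s), vectorised over `temperature`.
#' @export
mf_f_divergence <- function(temperature, mean_degree, l1_size = 1,
                            f_second_deriv = 1 / (2 * log(2))) {
  stopifnot(all(temperature > 0), l1_size >= 0, f_second_deriv > 0)
  delta <- ising_order_parameter(temperature, mean_degree)
  0.5 * f_second_deriv * l1_size * (1 - delta^4) / temperature^2
}

#' Tabulate the mean-field curve over a temperature grid
#'
#' @inheritParams potts_order_parameter
#' @param t_min,t_max Temperature range; defaults `[0.3, 3] * Tc`.
#' @param points Number of log-spaced grid points (default 200).
#' @param l1_size Perturbation size used for the divergence column.
#' @return Data frame with columns `temperature`, `t_over_tc`, `delta`,
#'   `divergence_mf` (the divergence column uses the Ising order parameter
#'   regardless of q, matching the expansion's Ising setting).
#' @export
mean_field_curve <- function(mean_degree, q = 2, t_min = NULL, t_max = NULL,
                             points = 200, l1_size = 1) {
  tc <- critical_temperature(mean_degree, q)
  if (is.null(t_min)) t_min <- 0.3 * tc
  if (is.null(t_max)) t_max <- 3 * tc
  Tgrid <- exp(seq(log(t_min), log(t_max), length.out = points))
  delta <- if (q == 2) ising_order_parameter(Tgrid, mean_degree)
           else potts_order_parameter(Tgrid, mean_degree, q)
  data.frame(temperature = Tgrid, t_over_tc = Tgrid / tc, delta = delta,
             divergence_mf = mf_f_divergence(Tgrid, mean_degree, l1_size))
}

#' Locate the maximum of the mean-field divergence curve
#'
#' Evaluates [mf_f_divergence()] on a fine uniform grid of `T/Tc` and
#' returns the argmax location.
#'
#' @inheritParams ising_order_parameter
#' @param t_rel_range Range of `T/Tc` to scan (default `c(0.5, 1.5)`).
#' @param points Grid resolution (default `10^4 + 1`).
#' @return List with `t_over_tc_max` (argmax location) and `value`.
#' @export
mf_divergence_maximum <- function(mean_degree = 40,
                                  t_rel_range = c(0.5, 1.5),
                                  points = 10001) {
  tc <- critical_temperature(mean_degree, 2)
  tau <- seq(t_rel_range[1], t_rel_range[2], length.out = points)
  d <- mf_f_divergence(tau * tc, mean_degree)
  k <- which.max(d)
  list(t_over_tc_max = tau[k], value = d[k])
}
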