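#' Declarative experiment configuration
#'
#' Bundles every knob of a benchmark run.  Temperature grids are given in
#' units of the mean-field critical temperature of the configured model
#' (the paper-style x-axis); absolute grids can be recovered by
#' multiplying by [critical_temperature()].
#'
#' @param kind One of `"discriminability"`, `"threshold_topology"`,
#'   `"rmse"`, `"potts_comparison"`.
#' @param n,mean_degree Graph size and mean degree.
#' @param q Number of states (or a vector of q values for
#'   `"potts_comparison"`).
#' @param temperatures_rel Temperature grid in units of Tc.
#' @param K Sample size(s); a vector evaluates nested subsets of one chain.
#' @param graph_seed Seed for the (single, fixed) graph.
#' @param replicate_seeds Integer vector; one full sampling/evaluation
#'   replicate per seed.
#' @param sampler `"gibbs"` or `"cftp"`.
#' @param ridge Ridge for [mean_field_inversion()] (`NULL` = default).
#' @param burn_in,thinning Gibbs settings.
#' @param validation_fraction,lp Threshold-selection settings.
#' @param fresh_graphs If `TRUE`, draw a fresh graph per replicate
#'   (ensemble error bars) instead of one fixed graph.
#' @return List of class `"experiment_config"`.
#' @export
experiment_config <- function(kind, n, mean_degree, q = 2,
                              temperatures_rel, K,
                              graph_seed = 1L, replicate_seeds = 1:3,
                              sampler = c("gibbs", "cftp"), ridge = NULL,
                              burn_in = 1000, thinning = 10,
                              validation_fraction = 0.2, lp = 2,
                              fresh_graphs = FALSE) {
  sampler <- match.arg(sampler)
  stopifnot(length(temperatures_rel) >= 1, all(temperatures_rel > 0),
            all(K >= 2), n >= 2)
  structure(list(kind = kind, n = n, mean_degree = mean_degree, q = q,
                 temperatures_rel = temperatures_rel, K = sort(K),
                 graph_seed = graph_seed, replicate_seeds = replicate_seeds,
                 sampler = sampler, ridge = ridge, burn_in = burn_in,
                 thinning = thinning,
                 validation_fraction = validation_fraction, lp = lp,
                 fresh_graphs = fresh_graphs),
            class = "experiment_config")
}

#' Shipped figure-style presets
#'
#' Parameter sets matching the study's experiment families, plus uniformly
#' scaled-down twins for quick runs: `scale > 1` divides `n` and `K` by the
#' factor (keeping `K >= 500`).  `"fig3a"`/`"fig3b"` require `n` since the
#' source legends do not fix it.
#'
#' @param name One of `"fig2"`, `"fig3a"`, `"fig3b"`, `"fig4"`, `"fig5"`,
#'   `"fig7"`.
#' @param n Vertex count override (required for fig3 presets).
#' @param scale Scale-down factor (default 1 = full size).
#' @param ... Overrides passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
preset <- function(name, n = NULL, scale = 1, ...) {
  base <- switch(name,
    fig2 = list(kind = "discriminability", n = 50, mean_degree = 20,
                temperatures_rel = c(0.7, 1.0, 1.5), K = 5e3),
    fig3a = list(kind = "discriminability", n = n, mean_degree = 40,
                 temperatures_rel = c(0.5, 0.7, 0.85, 1.0, 1.25, 1.5),
                 K = 2e3),
    fig3b = list(kind = "discriminability", n = n, mean_degree = 40,
                 temperatures_rel = c(0.5, 0.7, 0.85, 1.0, 1.25, 1.5),
                 K = 1e4),
    fig4 = list(kind = "threshold_topology", n = 400, mean_degree = 40,
                temperatures_rel = c(0.5, 0.7, 0.85, 1.0, 1.25, 1.5),
                K = 1e4),
    fig5 = list(kind = "rmse", n = 400, mean_degree = 40,
                temperatures_rel = c(0.5, 0.7, 0.85, 1.0, 1.25, 1.5),
                K = c(2e3, 1e4)),
    fig7 = list(kind = "potts_comparison", n = 400, mean_degree = 40,
                q = c(2, 3, 4),
                temperatures_rel = c(0.5, 0.7, 0.85, 1.0, 1.25, 1.5),
                K = 1e4),
    stop("unknown preset: ", name))
  if (is.null(base$n)) stop("preset ", name, " requires an explicit n")
  if (!is.null(n)) base$n <- n
  base$n <- max(4L, as.integer(round(base$n / scale)))
  base$K <- pmax(500, round(base$K / scale))
  do.call(experiment_config, utils::modifyList(base, list(...)))
}

draw_graph <- function(config, rep_seed) {
  gseed <- if (config$fresh_graphs) config$graph_seed + rep_seed
           else config$graph_seed
  generate_er_couplings(config$n, config$mean_degree, gseed)
}

sample_config <- function(config, J, temperature, K, seed, q = 2) {
  model <- spin_model(J, temperature, q = q)
  if (config$sampler == "cftp") sample_ising_exact(model, K, seed = seed)
  else sample_gibbs(model, K, seed = seed, burn_in = config$burn_in,
                    thinning = config$thinning)
}

score_both <- function(samples, J, temperature, ridge) {
  mom <- estimate_moments(samples)
  inv <- mean_field_inversion(mom, temperature = temperature, ridge = ridge)
  list(moments = mom, inferred = inv,
       local = local_scores(mom, truth = J),
       global = global_scores(inv, mom, truth = J))
}

#' Discriminability sweep (AUC of local vs global scores)
#'
#' For each temperature and replicate seed: draw samples from the fixed
#' graph's model, score all pairs locally (raw correlation) and globally
#' (direct correlation from mean-field inversion), and record both AUCs.
#' When `config$K` has several values, nested subsets of one chain are
#' evaluated at each size.
#'
#' @param config An `experiment_config`.
#' @return List of class `"experiment_result"` with `config` and a
#'   `records` data frame (`t_rel`, `temperature`, `K`, `seed`,
#'   `auc_local`, `auc_global`).
#' @export
run_discriminability <- function(config) {
  tc <- critical_temperature(config$mean_degree, 2)
  Kmax <- max(config$K)
  rows <- list()
  for (s in config$replicate_seeds) {
    J <- draw_graph(config, s)
    for (trel in config$temperatures_rel) {
      T <- trel * tc
      samples <- sample_config(config, J, T, Kmax, seed = s)
      for (K in config$K) {
        sc <- score_both(subset_samples(samples, K), J, T, config$ridge)
        rows[[length(rows) + 1]] <- data.frame(
          t_rel = trel, temperature = T, K = K, seed = s,
          auc_local = roc_curve(sc$local)$auc,
          auc_global = roc_curve(sc$global)$auc)
      }
    }
  }
  structure(list(config = config, records = do.call(rbind, rows)),
            class = "experiment_result")
}

#' Validation/test threshold selection and false-positive topology
#'
#' For each temperature and replicate: score pairs, split them at random
#' into validation and test sets, choose the threshold closest to the
#' ideal classifier on the validation ROC, and record test-set rates plus
#' the shortest-path histogram of distance-2 false positives for both
#' methods.
#'
#' @param config An `experiment_config`.
#' @return `experiment_result` with `records` (per method/T/replicate
#'   rates) and `fp_histograms`, a named list of
#'   [false_positive_topology()] reports keyed `method|t_rel|seed`.
#' @export
run_threshold_topology <- function(config) {
  tc <- critical_temperature(config$mean_degree, 2)
  J <- draw_graph(config, config$replicate_seeds[1])
  topo <- pair_topology(J)
  rows <- list()
  fps <- list()
  for (s in config$replicate_seeds) {
    for (trel in config$temperatures_rel) {
      T <- trel * tc
      samples <- sample_config(config, J, T, max(config$K), seed = s)
      sc <- score_both(samples, J, T, config$ridge)
      for (method in c("local", "global")) {
        scored <- sc[[method]]
        sp <- split_pairs(scored, config$validation_fraction, seed = s)
        rep <- threshold_by_closest_to_ideal(sp$validation, sp$test,
                                             p = config$lp)
        rows[[length(rows) + 1]] <- data.frame(
          method = method, t_rel = trel, temperature = T, seed = s,
          threshold = rep$threshold, tpr = rep$tpr, fpr = rep$fpr,
          positive_rate = rep$positive_rate,
          overprediction = rep$overprediction)
        fps[[paste(method, trel, s, sep = "|")]] <-
          false_positive_topology(rep, topo)
      }
    }
  }
  structure(list(config = config, records = do.call(rbind, rows),
                 fp_histograms = fps, topology = topo),
            class = "experiment_result")
}

#' RMS-error sweep of mean-field inversion
#'
#' Records, per (temperature, sample size, replicate), the rms error of the
#' de-dimensionalised inferred couplings `Jhat = T * beta_Jhat` against the
#' true 0/1 couplings, together with the per-class mean/variance
#' decomposition.
#'
#' @param config An `experiment_config`.
#' @return `experiment_result` with `records` columns `t_rel`,
#'   `temperature`, `K`, `seed`, `rmse`, `mean_class0`, `mean_class1`,
#'   `var_class0`, `var_class1`.
#' @export
run_rmse_sweep <- function(config) {
  tc <- critical_temperature(config$mean_degree, 2)
  Kmax <- max(config$K)
  rows <- list()
  for (s in config$replicate_seeds) {
    J <- draw_graph(config, s)
    for (trel in config$temperatures_rel) {
      T <- trel * tc
      samples <- sample_config(config, J, T, Kmax, seed = s)
      for (K in config$K) {
        mom <- estimate_moments(subset_samples(samples, K))
        inv <- mean_field_inversion(mom, temperature = T,
                                    ridge = config$ridge)
        rr <- rmse_report(inv, J)
        rows[[length(rows) + 1]] <- data.frame(
          t_rel = trel, temperature = T, K = K, seed = s, rmse = rr$rmse,
          mean_class0 = rr$mean_by_class[["0"]],
          mean_class1 = rr$mean_by_class[["1"]],
          var_class0 = rr$variance_by_class[["0"]],
          var_class1 = rr$variance_by_class[["1"]])
      }
    }
  }
  structure(list(config = config, records = do.call(rbind, rows)),
            class = "experiment_result")
}

#' Ising vs Potts discriminability comparison
#'
#' Runs the discriminability sweep for each `q` in `config$q` on the same
#' interaction graph, recording the AUC of local and global scores as a
#' function of temperature (in units of each model's own Tc) and of the
#' mean-field order parameter.  `q = 2` uses the +/-1 Ising pathway, so
#' with identical seeds it reproduces [run_discriminability()].
#'
#' @param config An `experiment_config` with `q` a vector from {2, 3, 4}.
#' @return `experiment_result`; `records` columns add `q` and `delta_mf`.
#' @export
run_potts_comparison <- function(config) {
  rows <- list()
  for (q in config$q) {
    tc <- critical_temperature(config$mean_degree, q)
    for (s in config$replicate_seeds) {
      J <- draw_graph(config, s)
      for (trel in config$temperatures_rel) {
        T <- trel * tc
        samples <- sample_config(config, J, T, max(config$K), seed = s, q = q)
        for (K in config$K) {
          sc <- score_both(subset_samples(samples, K), J, T, config$ridge)
          delta <- if (q == 2) ising_order_parameter(T, config$mean_degree)
                   else potts_order_parameter(T, config$mean_degree, q)
          rows[[length(rows) + 1]] <- data.frame(
            q = q, t_rel = trel, temperature = T, K = K, seed = s,
            delta_mf = delta,
            auc_local = roc_curve(sc$local)$auc,
            auc_global = roc_curve(sc$global)$auc)
        }
      }
    }
  }
  structure(list(config = config, records = do.call(rbind, rows)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result (%s): %d records\n", x$config$kind,
              nrow(x$records)))
  print(utils::head(x$records, 10))
  invisible(x)
}
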