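tiny_cfg <- function(kind = "discriminability", ...) {
  experiment_config(kind, n = 16, mean_degree = 5,
                    temperatures_rel = c(0.8, 1.2), K = 400,
                    graph_seed = 2, replicate_seeds = 1,
                    burn_in = 100, thinning = 2, ...)
}

test_that("run_discriminability runs end-to-end and is deterministic", {
  cfg <- tiny_cfg()
  res <- run_discriminability(cfg)
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$records), 2)          # one record per (T, K, seed)
  expect_true(all(c("auc_local", "auc_global") %in% names(res$records)))
  expect_true(all(res$records$auc_local >= 0 & res$records$auc_local <= 1))
  res2 <- run_discriminability(cfg)
  expect_identical(res$records, res2$records)

  # degenerate single-temperature single-seed config: one record
  cfg1 <- experiment_config("discriminability", n = 12, mean_degree = 4,
                            temperatures_rel = 1, K = 200, graph_seed = 1,
                            replicate_seeds = 7, burn_in = 50, thinning = 1)
  expect_equal(nrow(run_discriminability(cfg1)$records), 1)
})

test_that("presets carry the documented parameters and scale down", {
  f2 <- preset("fig2")
  expect_equal(f2$n, 50)
  expect_equal(f2$mean_degree, 20)
  expect_equal(f2$K, 5e3)
  expect_equal(f2$temperatures_rel, c(0.7, 1.0, 1.5))

  expect_equal(preset("fig3a", n = 400)$K, 2e3)
  expect_equal(preset("fig3b", n = 400)$K, 1e4)
  expect_error(preset("fig3a"), "requires an explicit n")

  f4 <- preset("fig4")
  expect_equal(f4$n, 400)
  expect_equal(f4$mean_degree, 40)
  expect_equal(f4$K, 1e4)
  expect_equal(f4$kind, "threshold_topology")

  expect_equal(preset("fig5")$K, c(2e3, 1e4))
  expect_equal(preset("fig7")$q, c(2, 3, 4))

  sc <- preset("fig4", scale = 8)
  expect_equal(sc$n, 50)
  expect_equal(sc$K, 1250)
})

test_that("run_rmse_sweep reports the class decomposition per cell", {
  res <- run_rmse_sweep(tiny_cfg("rmse"))
  expect_equal(nrow(res$records), 2)
  expect_true(all(res$records$rmse >= 0))
  expect_true(all(is.finite(res$records$mean_class1)))
})

test_that("run_threshold_topology produces valid rates and histograms", {
  res <- run_threshold_topology(tiny_cfg("threshold_topology"))
  r <- res$records
  expect_equal(nrow(r), 4)                     # 2 methods x 2 temperatures
  expect_true(all(r$tpr >= 0 & r$tpr <= 1))
  expect_true(all(r$fpr >= 0 & r$fpr <= 1))
  expect_true(all(r$positive_rate >= 0 & r$positive_rate <= 1))
  h <- res$fp_histograms[[1]]
  expect_s3_class(h, "fp_topology_report")
  expect_equal(sum(h$baseline$fraction), 1, tolerance = 1e-12)
})

test_that("potts comparison at q = 2 reproduces the Ising pathway", {
  cfg <- experiment_config("potts_comparison", n = 14, mean_degree = 4,
                           q = 2, temperatures_rel = c(0.9, 1.3), K = 300,
                           graph_seed = 3, replicate_seeds = 2,
                           burn_in = 100, thinning = 2)
  resp <- run_potts_comparison(cfg)
  cfg_ising <- cfg
  cfg_ising$kind <- "discriminability"
  resd <- run_discriminability(cfg_ising)
  expect_equal(resp$records$auc_local, resd$records$auc_local)
  expect_equal(resp$records$auc_global, resd$records$auc_global)
  expect_equal(resp$records$delta_mf,
               ising_order_parameter(resp$records$temperature, 4))

  cfg3 <- experiment_config("potts_comparison", n = 14, mean_degree = 4,
                            q = 3, temperatures_rel = c(0.9, 1.3), K = 300,
                            graph_seed = 3, replicate_seeds = 2,
                            burn_in = 100, thinning = 2)
  res3 <- run_potts_comparison(cfg3)
  expect_equal(nrow(res3$records), 2)
  expect_true(all(res3$records$auc_global > 0 & res3$records$auc_global < 1))
})

test_that("fp histograms right-shift near Tc for local inference", {
  # scaled-down qualitative check: at T ~ Tc false positives of local
  # scoring concentrate on better-connected distance-2 pairs
  cfg <- experiment_config("threshold_topology", n = 80, mean_degree = 16,
                           temperatures_rel = 0.9, K = 4000, graph_seed = 5,
                           replicate_seeds = 1, burn_in = 300, thinning = 5)
  res <- run_threshold_topology(cfg)
  h <- res$fp_histograms[["local|0.9|1"]]
  expect_false(h$no_false_positives)
  mean_fp <- sum(h$false_positives$num_shortest_paths * h$false_positives$fraction)
  mean_base <- sum(h$baseline$num_shortest_paths * h$baseline$fraction)
  expect_gt(mean_fp, mean_base)
})
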