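scored_df <- function(score, label) data.frame(i = seq_along(score),
                                               j = seq_along(score) + 100,
                                               score = score, label = label)

test_that("roc_curve reproduces worked examples and the brute-force oracle", {
  expect_equal(roc_curve(c(3, 2, 1), c(1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(2, 6), c(1, 0, 1, 0, 0, 1))$auc, 0.5)
  expect_equal(roc_curve(c(1, 2, 3), c(1, 0, 1))$auc, 0.5)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "positive and one negative")

  set.seed(41)
  for (rep in 1:30) {
    m <- sample(10:60, 1)
    score <- sample(seq(0, 1, 0.1), m, TRUE)   # tie-heavy
    label <- rbinom(m, 1, 0.4)
    if (sum(label) %in% c(0, m)) next
    r <- roc_curve(score, label)
    expect_equal(r$auc, brute_auc(score, label), tolerance = 1e-12)
    # curve invariants
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
    expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
    expect_equal(c(r$tpr[length(r$tpr)], r$fpr[length(r$fpr)]), c(1, 1))
    # trapezoid area over the tie-collapsed curve equals the rank AUC
    area <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
    expect_equal(area, r$auc, tolerance = 1e-12)
    # invariance under strictly monotone transformation
    expect_equal(roc_curve(exp(3 * score), label)$auc, r$auc)
  }
})

test_that("threshold_by_positive_count equates false positives and negatives", {
  sc <- scored_df(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  rep <- threshold_by_positive_count(sc)
  expect_equal(rep$tpr, 1)
  expect_equal(rep$fpr, 0)

  set.seed(42)
  for (k in 1:25) {
    m <- sample(8:40, 1)
    sc <- scored_df(sample(seq(0, 1, 0.2), m, TRUE), rbinom(m, 1, 0.5))
    if (sum(sc$label) %in% c(0, m)) next
    rep <- threshold_by_positive_count(sc, seed = k)
    fp <- sum(rep$predictions$predicted & rep$predictions$label == 0)
    fn <- sum(!rep$predictions$predicted & rep$predictions$label == 1)
    expect_equal(fp, fn)
    expect_equal(sum(rep$predictions$predicted), sum(sc$label))
  }

  # full tie, n_true = half the pairs: random tie-break gives tpr ~ 1/2
  sc <- scored_df(rep(1, 20), rep(c(1, 0), 10))
  tprs <- vapply(1:400, function(s)
    threshold_by_positive_count(sc, n_true = 10, seed = s)$tpr, numeric(1))
  # hypergeometric expectation 1/2, sd of the mean ~ 0.006
  expect_lt(abs(mean(tprs) - 0.5), 4 * sd(tprs) / sqrt(length(tprs)))
})

test_that("threshold_by_closest_to_ideal follows the validation ROC", {
  val <- scored_df(c(0.9, 0.7, 0.2, 0.1), c(1, 1, 0, 0))
  tst <- scored_df(c(0.8, 0.6, 0.3), c(1, 0, 0))
  rep <- threshold_by_closest_to_ideal(val, tst)
  expect_equal(unname(rep$validation_point), c(0, 1))

  # spec'd worked instance: equal-distance candidates resolved to the
  # lower threshold, giving validation (fpr, tpr) = (0.5, 1.0)
  val2 <- scored_df(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))
  rep2 <- threshold_by_closest_to_ideal(val2, tst)
  expect_equal(rep2$threshold, 0.4)
  expect_equal(unname(rep2$validation_point), c(0.5, 1.0))
  expect_equal(rep2$validation_distance, 0.5)

  # rank statistic: invariant under monotone score transformations
  val3 <- scored_df(runif(40), rbinom(40, 1, 0.5))
  tst3 <- scored_df(runif(30), rbinom(30, 1, 0.5))
  r1 <- threshold_by_closest_to_ideal(val3, tst3)
  val3t <- transform(val3, score = exp(2 * score))
  tst3t <- transform(tst3, score = exp(2 * score))
  r2 <- threshold_by_closest_to_ideal(val3t, tst3t)
  expect_equal(r1$tpr, r2$tpr)
  expect_equal(r1$fpr, r2$fpr)

  expect_error(threshold_by_closest_to_ideal(scored_df(1:3, c(1, 1, 1)), tst),
               "positive and one negative")
})

test_that("split_pairs partitions pairs at the requested fraction", {
  sc <- scored_df(runif(50), rbinom(50, 1, 0.3))
  sp <- split_pairs(sc, 0.2, seed = 4)
  expect_equal(nrow(sp$validation), 10)
  expect_equal(nrow(sp$test), 40)
  expect_setequal(c(sp$validation$i, sp$test$i), sc$i)
})

test_that("rmse_report computes the exact class decomposition", {
  J <- generate_er_couplings(12, 4, seed = 5)
  expect_equal(rmse_report(unclass(J) * 1.0, J)$rmse, 0)
  expect_equal(rmse_report(unclass(J) + 0.5, J)$rmse, 0.5)

  set.seed(44)
  for (k in 1:10) {
    Jh <- matrix(rnorm(144), 12, 12)
    Jh <- (Jh + t(Jh)) / 2
    r <- rmse_report(Jh, J)
    w <- r$count_by_class / sum(r$count_by_class)
    expect_equal(r$rmse^2,
                 sum(w * (r$bias_by_class^2 + r$variance_by_class)),
                 tolerance = 1e-12)
  }
})

test_that("false_positive_topology isolates distance-2 pairs", {
  G <- planted_motif_graph(c(5, 2))
  topo <- pair_topology(G)
  sc <- data.frame(i = topo$i, j = topo$j, score = 0, label = topo$label)
  # classifier that predicts only the 5-common-neighbour hub pair
  sc$score[sc$i == 1 & sc$j == 2] <- 1
  sc$score[sc$label == 1] <- 2
  rep <- threshold_by_positive_count(sc, n_true = sum(sc$label) + 1, seed = 1)
  fpt <- false_positive_topology(rep, topo)
  expect_false(fpt$no_false_positives)
  expect_equal(fpt$false_positives$fraction[fpt$false_positives$num_shortest_paths == 5], 1)
  expect_equal(sum(fpt$baseline$fraction), 1)

  # random guessing: the two histograms agree within multinomial error
  set.seed(46)
  J <- generate_er_couplings(60, 10, seed = 6)
  topo <- pair_topology(J)
  sc <- data.frame(i = topo$i, j = topo$j, score = runif(nrow(topo)),
                   label = topo$label)
  rep <- threshold_by_positive_count(sc, n_true = 600, seed = 2)
  fpt <- false_positive_topology(rep, topo)
  nfp <- sum(fpt$false_positives$count)
  se <- sqrt(fpt$baseline$fraction * (1 - fpt$baseline$fraction) / nfp)
  expect_true(all(abs(fpt$false_positives$fraction - fpt$baseline$fraction)
                  <= 4 * se + 1e-9))
})

test_that("contact map export encodes predictions", {
  sc <- scored_df(c(0.9, 0.5, 0.1), c(1, 0, 1))
  sc$i <- 1:3; sc$j <- c(4, 5, 6)
  rep <- threshold_by_positive_count(sc, n_true = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(rep, 6, path)
  M <- unname(as.matrix(read.table(path, sep = "\t")))
  expect_equal(M[1, 4], 0)   # true positive
  expect_equal(M[2, 5], 1)   # false positive
  expect_equal(M[3, 6], 2)   # false negative
  expect_equal(M[4, 1], 0)   # mirrored
})
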