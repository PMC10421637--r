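chain_model <- function(n, beta) chain_fixture(n, beta)$model

test_that("estimate_moments computes plug-in means and connected correlations", {
  # constant all-up samples
  X <- matrix(1L, 50, 4)
  mom <- estimate_moments(X)
  expect_equal(mom$means, rep(1, 4))
  expect_equal(mom$connected_correlations, matrix(0, 4, 4))

  # perfectly anticorrelated zero-mean pair
  X2 <- cbind(rep(c(1L, -1L), 20), rep(c(-1L, 1L), 20))
  mom2 <- estimate_moments(X2)
  expect_equal(mom2$connected_correlations[1, 2], -1)
  expect_equal(mom2$means, c(0, 0))

  # chain samples vs the enumeration oracle
  m <- chain_model(3, 1)
  ex <- exact_moments(m)
  s <- sample_gibbs(m, 20000, seed = 21)
  mom3 <- estimate_moments(s)
  se <- sqrt((1 - ex$second_moments^2) / nrow(s)) + 1e-12
  expect_true(all(abs(mom3$second_moments - ex$second_moments) <= 4 * se))
})

test_that("mean_field_inversion matches closed forms and flags singularity", {
  # independent spins: C = I -> no couplings
  mom <- structure(list(q = 2L, n = 3, K = 1000, means = rep(0, 3),
                        second_moments = diag(3),
                        connected_correlations = diag(3)),
                   class = "moment_estimates")
  inv <- mean_field_inversion(mom, ridge = 0)
  expect_equal(inv$beta_J, matrix(0, 3, 3))

  # exact two-spin inversion: beta_Jhat = t / (1 - t^2)
  for (bJ in c(0.1, 0.5, 1)) {
    fx <- two_spin_fixture(bJ)
    em <- exact_moments(fx$model)
    got <- mean_field_inversion(em, ridge = 0)$beta_J[1, 2]
    t <- tanh(bJ)
    expect_equal(got, t / (1 - t^2), tolerance = 1e-10)
  }
  fx <- two_spin_fixture(0.1)
  expect_equal(mean_field_inversion(exact_moments(fx$model), ridge = 0)$beta_J[1, 2],
               0.100668, tolerance = 1e-4)

  # exact-moment inversion equals the adjugate oracle (n = 2, 3)
  for (n in 2:3) {
    m <- chain_model(n, 0.6)
    em <- exact_moments(m)
    inv <- mean_field_inversion(em, ridge = 0)
    oracle <- -adjugate_inverse(em$connected_correlations)
    diag(oracle) <- 0
    expect_equal(inv$beta_J, oracle, tolerance = 1e-10)
  }

  # K < n with ridge 0 must raise a singularity error naming the rank
  X <- matrix(sample(c(-1L, 1L), 5 * 10, TRUE), 5, 10)
  expect_error(mean_field_inversion(estimate_moments(X), ridge = 0),
               "singular \\(rank")
})

test_that("local scores rank direct above indirect correlations", {
  m <- chain_model(3, 0.8)
  em <- exact_moments(m)
  truth <- m$couplings
  ls <- local_scores(em, truth = truth)
  s12 <- ls$score[ls$i == 1 & ls$j == 2]
  s23 <- ls$score[ls$i == 2 & ls$j == 3]
  s13 <- ls$score[ls$i == 1 & ls$j == 3]
  expect_equal(s12, s23, tolerance = 1e-12)
  expect_gt(s12, s13)
  expect_gt(s13, 0)

  # all-equal samples: complete tie at score 1
  X <- matrix(1L, 20, 3)
  expect_equal(local_scores(estimate_moments(X))$score, rep(1, 3))
})

test_that("direct_pair_model matches marginals and closed forms", {
  # bJ = 0: factorised model
  dm <- direct_pair_model(0, c(0.3, -0.4))
  expect_equal(dm$matching_fields, atanh(c(0.3, -0.4)), tolerance = 1e-8)
  expect_equal(dm$direct_correlation, 0.3 * -0.4, tolerance = 1e-8)

  # zero means: corr = tanh(bJ)
  dm2 <- direct_pair_model(0.7, c(0, 0))
  expect_equal(dm2$matching_fields, c(0, 0), tolerance = 1e-8)
  expect_equal(dm2$direct_correlation, tanh(0.7), tolerance = 1e-8)

  # random triples: refitted marginals equal the targets
  set.seed(31)
  for (k in 1:100) {
    bJ <- runif(1, -2, 2)
    m <- runif(2, -0.95, 0.95)
    dm <- direct_pair_model(bJ, m)
    h <- dm$matching_fields
    w <- exp(c(bJ + h[1] + h[2], -bJ + h[1] - h[2],
               -bJ - h[1] + h[2], bJ - h[1] - h[2]))
    Z <- sum(w)
    expect_equal((w[1] + w[2] - w[3] - w[4]) / Z, m[1], tolerance = 1e-8)
    expect_equal((w[1] - w[2] + w[3] - w[4]) / Z, m[2], tolerance = 1e-8)
  }

  expect_warning(dm3 <- direct_pair_model(0.5, c(1, 0.2)), "degenerate")
  expect_equal(dm3$direct_correlation, 0.2)
})

test_that("global scores suppress indirect correlations and respect symmetry", {
  m <- chain_model(3, 0.8)
  em <- exact_moments(m)
  truth <- m$couplings
  inv <- mean_field_inversion(em, ridge = 0)
  gs <- global_scores(inv, em, truth = truth)
  ls <- local_scores(em, truth = truth)
  g13 <- gs$score[gs$i == 1 & gs$j == 3]
  l13 <- ls$score[ls$i == 1 & ls$j == 3]
  expect_lt(abs(g13), abs(l13))   # direct score of the indirect pair shrinks

  # monotone in bJ at zero means
  mf <- vapply(c(0.1, 0.5, 1, 2), function(b)
    direct_pair_model(b, c(0, 0))$direct_correlation, numeric(1))
  expect_true(all(diff(mf) > 0))

  # invariance under a global spin flip of the sample set
  s <- sample_gibbs(m, 2000, seed = 33)
  momA <- estimate_moments(unclass(s))
  momB <- estimate_moments(-unclass(s))
  invA <- mean_field_inversion(momA)
  invB <- mean_field_inversion(momB)
  expect_equal(local_scores(momA)$score, local_scores(momB)$score,
               tolerance = 1e-12)
  expect_equal(global_scores(invA, momA)$score,
               global_scores(invB, momB)$score, tolerance = 1e-8)
})

test_that("Potts scoring is gauge invariant in the dropped reference state", {
  J <- matrix(0L, 4, 4)
  J[1, 2] <- J[2, 1] <- J[2, 3] <- J[3, 2] <- J[3, 4] <- J[4, 3] <- 1L
  mp <- spin_model(J, 1.2, q = 3)
  frob_by_drop <- function(drop) {
    em <- exact_moments(mp, drop_state = drop)
    inv <- mean_field_inversion(em, ridge = 0)
    gs <- global_scores(inv, em)
    list(global = gs$score, local = local_scores(em)$score)
  }
  ref <- frob_by_drop(3)
  for (drop in 1:2) {
    alt <- frob_by_drop(drop)
    expect_equal(alt$global, ref$global, tolerance = 1e-8)
    expect_equal(alt$local, ref$local, tolerance = 1e-8)
  }
  # zero-sum gauge blocks have vanishing row/column sums
  em <- exact_moments(mp)
  inv <- mean_field_inversion(em, ridge = 0)
  B <- coupling_block(inv, 1, 2)
  expect_equal(rowSums(B), rep(0, 3), tolerance = 1e-10)
  expect_equal(colSums(B), rep(0, 3), tolerance = 1e-10)
})

test_that("inversion recovers coupling ranks at high temperature", {
  lam <- 6
  J <- generate_er_couplings(20, lam, seed = 8)
  model <- spin_model(J, 2 * lam)     # T = 2 Tc
  s <- sample_gibbs(model, 1e5, seed = 9, burn_in = 200, thinning = 2)
  mom <- estimate_moments(s)
  inv <- mean_field_inversion(mom)
  pairs <- which(upper.tri(J), arr.ind = TRUE)
  x <- inv$beta_J[pairs]
  y <- unclass(J)[pairs]
  # Spearman against a two-valued target is capped at the perfect-separation
  # value (~0.81 at this edge density), so correlation is asserted as
  # Pearson, plus near-perfect rank separation via the AUC.
  expect_gt(cor(x, y), 0.9)
  expect_gt(roc_curve(x, y)$auc, 0.99)
})
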