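#' ROC curve and AUC of scored pairs
#'
#' Traces true- and false-positive rates over all distinct score
#' thresholds (rule: positive when `score >= threshold`), collapsing tied
#' scores into single diagonal segments.  The AUC is computed as the
#' Mann–Whitney statistic — the probability that a random positive
#' outscores a random negative, ties counted one half — which equals the
#' trapezoid area of the tie-collapsed curve.
#'
#' @param scored Data frame with columns `score` and `label` (0/1), e.g.
#'   from [local_scores()]; alternatively a numeric score vector.
#' @param labels 0/1 labels when `scored` is a plain vector.
#' @return List of class `"roc_curve"`: `thresholds` (descending, starting
#'   at `Inf` for the (0,0) point), `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(scored, labels = NULL) {
  if (is.data.frame(scored)) {
    scores <- scored$score
    labels <- scored$label
  } else scores <- scored
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("ROC analysis needs at least one positive and one negative pair")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(1 - l)[grp_end]
  structure(list(thresholds = c(Inf, s[grp_end]),
                 tpr = c(0, tp / P), fpr = c(0, fp / N), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

new_classification_report <- function(scored, predicted, threshold,
                                      tie_note = NULL) {
  lab <- scored$label
  tp <- sum(predicted & lab == 1)
  fp <- sum(predicted & lab == 0)
  P <- sum(lab == 1)
  N <- sum(lab == 0)
  structure(list(threshold = threshold,
                 tpr = tp / P, fpr = fp / N,
                 positive_rate = mean(predicted),
                 overprediction = (sum(predicted) - P) / P,
                 n_predicted = sum(predicted),
                 n_true = P,
                 tie_note = tie_note,
                 predictions = cbind(scored, predicted = predicted)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: threshold = %g, tpr = %.3f, fpr = %.3f, positive rate = %.3f\n",
              x$threshold, x$tpr, x$fpr, x$positive_rate))
  invisible(x)
}

#' Threshold so that positive predictions match the true edge count
#'
#' Sets the discrimination threshold so that exactly `n_true` pairs are
#' predicted positive, which makes the number of false positives equal the
#' number of false negatives.  Ties at the boundary are resolved by a
#' seeded uniform draw among the tied pairs.
#'
#' @param scored Data frame with `score` and `label` columns.
#' @param n_true Number of positives to predict; defaults to the number of
#'   true interactions.
#' @param seed RNG seed for boundary tie-breaking.
#' @return A `classification_report`; `$predictions` records per-pair
#'   predicted status.
#' @export
threshold_by_positive_count <- function(scored, n_true = NULL, seed = NULL) {
  if (is.null(n_true)) n_true <- sum(scored$label == 1)
  stopifnot(n_true <= nrow(scored))
  if (!is.null(seed)) set.seed(seed)
  s <- scored$score
  predicted <- rep(FALSE, length(s))
  tie_note <- NULL
  if (n_true > 0) {
    thr <- sort(s, decreasing = TRUE)[n_true]
    above <- which(s > thr)
    ties <- which(s == thr)
    need <- n_true - length(above)
    pick <- if (need > 0) {
      if (length(ties) > need) {
        tie_note <- sprintf("%d of %d tied pairs at score %g chosen at random",
                            need, length(ties), thr)
        sample(ties, need)
      } else ties
    } else integer(0)
    predicted[c(above, pick)] <- TRUE
  } else thr <- Inf
  new_classification_report(scored, predicted, thr, tie_note)
}

#' Validation-set threshold closest to the ideal classifier
#'
#' Chooses, on the validation ROC curve, the threshold whose (fpr, tpr)
#' point minimises the lp distance to the ideal corner (0, 1) — Euclidean
#' by default — then reports classification quality on the disjoint test
#' set with the rule `score >= threshold`.  Among equal-distance candidates
#' the lower threshold (more positives) wins.
#'
#' @param validation,test Disjoint scored-pair data frames from the same
#'   scoring run (see [split_pairs()]).
#' @param p Exponent of the lp distance in ROC space (default 2).
#' @return A `classification_report` on the test set, with extra fields
#'   `validation_point` (fpr, tpr achieved on validation) and
#'   `validation_distance`.
#' @export
threshold_by_closest_to_ideal <- function(validation, test, p = 2) {
  roc <- roc_curve(validation)
  d <- (roc$fpr^p + (1 - roc$tpr)^p)^(1 / p)
  best <- which(d <= min(d) + 1e-15)
  k <- best[which.min(roc$thresholds[best])]  # lower threshold on ties
  thr <- roc$thresholds[k]
  rep <- new_classification_report(test, test$score >= thr, thr)
  rep$validation_point <- c(fpr = roc$fpr[k], tpr = roc$tpr[k])
  rep$validation_distance <- d[k]
  rep
}

#' Randomly split scored pairs into validation and test sets
#'
#' @param scored Scored-pair data frame.
#' @param validation_fraction Fraction of pairs for validation (default
#'   0.2), chosen uniformly at random (not stratified).
#' @param seed RNG seed recorded with the split.
#' @return List with `validation` and `test` data frames; every pair lands
#'   in exactly one.
#' @export
split_pairs <- function(scored, validation_fraction = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(scored)
  nv <- round(validation_fraction * m)
  idx <- sample.int(m, nv)
  list(validation = scored[idx, , drop = FALSE],
       test = scored[-idx, , drop = FALSE])
}

#' Root-mean-square error of inferred couplings
#'
#' RMS error of `Jhat_ij - J_ij` over unordered pairs, with the per-class
#' (true 0 vs true 1) mean/variance decomposition: `rmse^2` equals the
#' class-frequency-weighted sum of squared bias plus variance (plug-in
#' variances, so the identity is exact).
#'
#' @param inferred De-dimensionalised inferred coupling matrix `Jhat`
#'   (e.g. `mean_field_inversion(mom, temperature = T)$J`), or an
#'   `inferred_couplings` object carrying `J`.
#' @param truth Ground-truth `coupling_matrix`.
#' @return List of class `"rmse_report"`: `rmse`, `bias_by_class`,
#'   `mean_by_class`, `variance_by_class`, `count_by_class`.
#' @export
rmse_report <- function(inferred, truth) {
  J_hat <- if (inherits(inferred, "inferred_couplings")) {
    if (is.null(inferred$J))
      stop("inferred_couplings lacks de-dimensionalised J; pass temperature to mean_field_inversion()")
    inferred$J
  } else inferred
  stopifnot(all(dim(J_hat) == dim(truth)))
  ut <- upper.tri(truth)
  x <- J_hat[ut]
  y <- unclass(truth)[ut]
  rmse <- sqrt(mean((x - y)^2))
  cls <- sort(unique(y))
  mean_c <- vapply(cls, function(c) mean(x[y == c]), numeric(1))
  var_c <- vapply(cls, function(c) {
    v <- x[y == c]; mean((v - mean(v))^2)
  }, numeric(1))
  cnt <- vapply(cls, function(c) sum(y == c), numeric(1))
  names(mean_c) <- names(var_c) <- names(cnt) <- cls
  structure(list(rmse = rmse,
                 mean_by_class = mean_c,
                 bias_by_class = mean_c - cls,
                 variance_by_class = var_c,
                 count_by_class = cnt),
            class = "rmse_report")
}

#' @export
print.rmse_report <- function(x, ...) {
  cat(sprintf("rmse_report: rmse = %.4f\n", x$rmse))
  for (c in names(x$mean_by_class))
    cat(sprintf("  class %s: mean %.4f, var %.5f (n = %d)\n", c,
                x$mean_by_class[[c]], x$variance_by_class[[c]],
                as.integer(x$count_by_class[[c]])))
  invisible(x)
}

#' Shortest-path histogram of distance-2 false positives
#'
#' Among noninteracting pairs at graph distance two (where the shortest-path
#' count equals the number of common neighbours), compares the histogram of
#' shortest-path counts of the false-positive pairs against the baseline
#' histogram of all such pairs.  Both raw counts and normalised fractions
#' are reported.
#'
#' @param report A `classification_report` whose `$predictions` carry `i`,
#'   `j` columns.
#' @param topology Output of [pair_topology()] for the same graph.
#' @return List of class `"fp_topology_report"`: data frames
#'   `false_positives` and `baseline` (columns `num_shortest_paths`,
#'   `count`, `fraction`), and flag `no_false_positives`.
#' @export
false_positive_topology <- function(report, topology) {
  pred <- report$predictions
  key <- function(df) paste(df$i, df$j)
  topo2 <- topology[topology$graph_distance == 2 & topology$label == 0, ]
  fp <- pred[pred$predicted & pred$label == 0, ]
  fp2 <- topo2[key(topo2) %in% key(fp), ]
  hist_of <- function(paths, levels) {
    cnt <- vapply(levels, function(m) sum(paths == m), numeric(1))
    data.frame(num_shortest_paths = levels, count = cnt,
               fraction = if (sum(cnt) > 0) cnt / sum(cnt) else cnt)
  }
  levels <- sort(unique(topo2$num_shortest_paths))
  structure(list(false_positives = hist_of(fp2$num_shortest_paths, levels),
                 baseline = hist_of(topo2$num_shortest_paths, levels),
                 no_false_positives = nrow(fp2) == 0),
            class = "fp_topology_report")
}

#' Export a contact map with prediction codes
#'
#' Tab-separated `n x n` integer matrix: -1 background (true negative),
#' 0 true positive, 1 false positive, 2 false negative.  Upper and lower
#' triangles can carry two methods' reports for side-by-side rendering.
#'
#' @param upper,lower `classification_report`s (lower may be `NULL` to
#'   mirror the upper one).
#' @param n Number of vertices.
#' @param path Output file.
#' @export
write_contact_map <- function(upper, n, path, lower = NULL) {
  if (is.null(lower)) lower <- upper
  M <- matrix(-1L, n, n)
  fill <- function(M, rep, transpose) {
    p <- rep$predictions
    code <- ifelse(p$predicted & p$label == 1, 0L,
                   ifelse(p$predicted & p$label == 0, 1L,
                          ifelse(!p$predicted & p$label == 1, 2L, -1L)))
    idx <- if (transpose) cbind(p$j, p$i) else cbind(p$i, p$j)
    M[idx] <- code
    M
  }
  M <- fill(M, upper, FALSE)
  M <- fill(M, lower, TRUE)
  write.table(M, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialise a report as JSON
#'
#' @param x Any report object (classification, rmse, divergence, ...).
#' @param path Output file.
#' @export
write_report_json <- function(x, path) {
  x <- unclass(x)
  x$predictions <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
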