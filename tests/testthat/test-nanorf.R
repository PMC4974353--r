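test_that("ROC AUC: worked example, separation, ties, pROC cross-check", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_equal(roc_auc(c(1, 0.9, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), class = "nrf_validation_error")

  set.seed(5)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    s <- round(runif(n), 1)  # force ties
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(l) || all(l)) next
    oracle <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                             direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(roc_auc(s, l), oracle)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(6)
  s <- runif(40)
  l <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.3, 0.7))
  a <- roc_auc(s, l)
  expect_equal(roc_auc(exp(3 * s), l), a)
  expect_equal(roc_auc(rank(s, ties.method = "average"), l), a)
})

test_that("MCC: worked confusion table, degenerate denominators, label-swap negation", {
  # confusion (TP=3, FP=1, TN=5, FN=1) at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.4, 0.3, 0.2, 0.1, 0.05)
  labels <- c(rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(mcc_at_threshold(scores, labels, 0.5), 14 / 24)
  # perfect split
  expect_equal(mcc_at_threshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE), 0.5), 1)
  # all predicted positive -> zero denominator rule
  expect_equal(mcc_at_threshold(scores, labels, 0), 0)
  # swapping labels negates MCC
  set.seed(7)
  for (i in 1:20) {
    s <- round(runif(12), 1)
    l <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (!any(l) || all(l)) next
    t <- runif(1)
    expect_equal(mcc_at_threshold(s, !l, t), -mcc_at_threshold(s, l, t))
    expect_lte(abs(mcc_at_threshold(s, l, t)), 1)
  }
})

test_that("best threshold scans score midpoints with smallest-threshold tie-break", {
  bt <- best_threshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bt$threshold, 0.5)  # midpoint of 0.2 and 0.8
  expect_equal(bt$mcc, 1)

  all_eq <- best_threshold(rep(0.4, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(all_eq$threshold, 0)
  expect_equal(all_eq$mcc, 0)

  # one positive at top rank among 10 separates perfectly
  one_top <- best_threshold(c(0.95, runif(9, 0, 0.5)), c(TRUE, rep(FALSE, 9)))
  expect_equal(one_top$mcc, 1)
})

test_that("ROC points run monotonically from (0,0) to (1,1) and integrate to the AUC", {
  set.seed(8)
  s <- round(runif(25), 1)
  l <- sample(c(TRUE, FALSE), 25, replace = TRUE, prob = c(0.4, 0.6))
  pts <- roc_points(s, l)
  expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(pts[nrow(pts), ], data.frame(fpr = 1, tpr = 1),
               ignore_attr = TRUE)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  trapezoid <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  expect_equal(trapezoid, roc_auc(s, l))
})

test_that("fractionate separates a planted complex perfectly at low noise", {
  sep <- separable_profile()
  res <- fractionate(sep$profile, sep$ts, rf_config(n_trees = 300, seed = 1))
  expect_s3_class(res, "fractionation_result")
  expect_equal(res$auc, 1)
  expect_equal(res$best_mcc, 1)
  expect_true(all(res$scores >= 0 & res$scores <= 1))
  expect_equal(sum(res$in_training == "positive"), 5)
  # background proteins sit at hitchhiker level, members score high
  expect_gt(min(res$scores[sprintf("POS%02d", 1:5)]),
            max(res$scores[sprintf("BG%03d", 1:20)]))
})

test_that("fractionate is seed-reproducible and independent of row order", {
  sep <- separable_profile(sd = 0.4)
  cfg <- rf_config(n_trees = 200, seed = 9)
  r1 <- fractionate(sep$profile, sep$ts, cfg)
  r2 <- fractionate(sep$profile, sep$ts, cfg)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$threshold, r2$threshold)

  shuffled <- sep$profile
  perm <- sample(nrow(shuffled$values))
  shuffled$values <- shuffled$values[perm, , drop = FALSE]
  shuffled$replicate_counts <- shuffled$replicate_counts[perm, , drop = FALSE]
  shuffled$proteins <- shuffled$proteins[perm, , drop = FALSE]
  r3 <- fractionate(shuffled, sep$ts, cfg)
  expect_identical(r1$scores, r3$scores)

  expect_error(
    fractionate(sep$profile, training_set("tiny", "POS01", c("NEG01", "NEG02")),
                cfg),
    class = "nrf_training_error")
  expect_error(fractionate(impute_missing(sep$profile), sep$ts, "not a config"))
})

test_that("fractionate refuses profiles with missing cells", {
  sep <- separable_profile()
  sep$profile$values[1, 1] <- NA
  expect_error(fractionate(sep$profile, sep$ts), "impute",
               class = "nrf_value_error")
})

test_that("random labels on background proteins give chance-level AUC", {
  set.seed(10)
  values <- matrix(rnorm(60 * 4, sd = 0.5), 60, 4,
                   dimnames = list(sprintf("BG%03d", 1:60), paste0("C", 1:4)))
  prof <- profile_from_matrix(values)
  aucs <- vapply(1:40, function(i) {
    ids <- sample(rownames(values), 14)
    ts <- training_set("random", ids[1:4], ids[5:14])
    fractionate(prof, ts, rf_config(n_trees = 150, seed = i))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("planted positives outscore hitchhikers across seeds at moderate noise", {
  hits <- vapply(1:20, function(seed) {
    sep <- separable_profile(pos_mean = -2, sd = 0.5, seed = seed)
    res <- fractionate(sep$profile, sep$ts, rf_config(n_trees = 300, seed = seed))
    mean(res$scores[sep$ts$positives]) >
      mean(res$scores[sprintf("BG%03d", 1:20)])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("labeled proteins never out-of-bag fall back to full-forest votes with a warning", {
  sep <- separable_profile(n_pos = 8, n_neg = 12)
  expect_warning(
    res <- fractionate(sep$profile, sep$ts, rf_config(n_trees = 3, seed = 2)),
    "out-of-bag")
  expect_true(all(is.finite(res$scores)))
})

test_that("scatter pairs join two fractionations and apply dual thresholds", {
  ids <- sprintf("P%02d", 1:6)
  sa <- stats::setNames(c(0.9, 0.5, 0.29, 0.1, 0.31, 0.27), ids)
  sb <- stats::setNames(c(0.8, 0.31, 0.6, 0.05, 0.29, 0.31), ids)
  fa <- fr_stub("condensin_I", sa)
  fb <- fr_stub("condensin_II", sb)
  tab <- scatter_pairs(fa, fb, thresholds = c(0.28, 0.3))
  expect_equal(tab$protein_id, sort(ids))
  # exactly the proteins above 0.28 in a AND 0.3 in b
  expect_equal(tab$protein_id[tab$above_both], c("P01", "P02", "P03"))

  same <- scatter_pairs(fa, fa)
  expect_equal(same$score_a, same$score_b)

  expect_error(scatter_pairs(fa, fr_stub("other", c(QQ = 0.5))),
               class = "nrf_validation_error")
})

test_that("members of two disjoint planted complexes occupy opposite scatter corners", {
  set.seed(11)
  ids <- c(sprintf("A%02d", 1:5), sprintf("B%02d", 1:5), sprintf("N%02d", 1:12),
           sprintf("BG%03d", 1:40))
  mu <- cbind(
    c(rep(-2.5, 5), rep(0, 5), rep(0, 52)),
    c(rep(0, 5), rep(-2.5, 5), rep(0, 52))
  )
  values <- matrix(rnorm(62 * 2, mean = mu, sd = 0.2), 62, 2,
                   dimnames = list(ids, c("KOA", "KOB")))
  prof <- profile_from_matrix(values)
  negs <- sprintf("N%02d", 1:12)
  ra <- fractionate(prof, training_set("A", sprintf("A%02d", 1:5), negs),
                    rf_config(n_trees = 300, seed = 1))
  rb <- fractionate(prof, training_set("B", sprintf("B%02d", 1:5), negs),
                    rf_config(n_trees = 300, seed = 2))
  tab <- scatter_pairs(ra, rb)
  a_rows <- tab$protein_id %in% sprintf("A%02d", 1:5)
  b_rows <- tab$protein_id %in% sprintf("B%02d", 1:5)
  expect_true(all(tab$score_a[a_rows] > 0.5 & tab$score_b[a_rows] < 0.5))
  expect_true(all(tab$score_b[b_rows] > 0.5 & tab$score_a[b_rows] < 0.5))
})
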