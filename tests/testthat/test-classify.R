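# Classification protocols: splits, classifiers, Monte Carlo averaging,
# and the confusion-report accuracy convention.

test_that("subject-level half splits respect sizes, balance, and seeding", {
  meta <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:47), each = 4),
    group = rep(rep(c("ctrl", "tin"), c(15, 32)), each = 4),
    stringsAsFactors = FALSE)
  sp <- split_half(meta, seed = 1)
  train_subj <- unique(meta$subject_id[sp$train])
  tab <- table(meta$group[match(train_subj, meta$subject_id)])
  expect_identical(as.integer(tab[c("ctrl", "tin")]), c(8L, 16L))
  # no subject on both sides
  expect_false(any(sp$train & sp$test))
  expect_true(all(sp$train | sp$test))

  spb <- split_half(meta, balance = TRUE, seed = 1)
  tr_b <- unique(meta$subject_id[spb$train])
  tab_b <- table(meta$group[match(tr_b, meta$subject_id)])
  expect_identical(unname(tab_b["ctrl"]), unname(tab_b["tin"]))

  expect_identical(split_half(meta, seed = 3), split_half(meta, seed = 3))
  expect_error(split_half(data.frame(subject_id = c("a", "b"),
                                     group = c("g1", "g2"))), "too small")
})

test_that("all five classifiers separate a 3-SD planted cohort", {
  for (cl in c("linear_svm", "quadratic_svm", "lda", "qda", "plsda")) {
    accs <- vapply(1:20, function(seed) {
      d <- separable_runs(n_subj_a = 10L, n_subj_b = 10L, n_feat = 10L,
                          n_shifted = 4L, effect = 3, seed = seed)
      sp <- split_half(d$meta, seed = seed + 100)
      pred <- fit_predict(cl, d$features[sp$train, ], d$meta$group[sp$train],
                          d$features[sp$test, ])
      mean(pred == d$meta$group[sp$test])
    }, 0)
    expect_gte(mean(accs), 0.95)
  }
})

test_that("LDA on a symmetric two-cluster instance is nearest-class-mean", {
  # isotropic within-class scatter (cross-shaped clusters), so the LDA
  # boundary is the perpendicular bisector of the class means at x = 2
  cross <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  train <- rbind(cross, sweep(cross, 2, c(-4, 0)))
  y <- rep(c("a", "b"), each = 4)
  test <- rbind(c(1, 0.5), c(3, 0.5), c(1.9, 0.5), c(2.1, 0.5))
  pred <- fit_predict("lda", train, y, test)
  expect_identical(as.character(pred), c("a", "b", "a", "b"))
})

test_that("PLS-DA agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  x <- matrix(rnorm(60 * 8), 60); colnames(x) <- paste0("f", 1:8)
  y <- ifelse(rowSums(x[, 1:3]) + rnorm(60) > 0, 1, -1)
  fit <- cyclicity:::.pls1_fit(x, y, 5)
  own <- cyclicity:::.pls1_predict(fit, x)
  ref <- mixOmics::pls(x, y, ncomp = 5, scale = FALSE, mode = "regression")
  refp <- predict(ref, x)$predict[, 1, 5]
  expect_equal(unname(own), unname(refp), tolerance = 1e-6)
})

test_that("exchangeable balanced groups classify at chance; unbalanced null is majority-biased", {
  d <- separable_runs(n_subj_a = 6, n_subj_b = 14, effect = 0, seed = 21)
  pr <- classification_protocol("raw", "linear_svm", n_trials = 60,
                                balance_classes = TRUE, seed = 31)
  rep_b <- monte_carlo_classification(d$features, d$meta, pr)
  se <- sd(rep_b$per_trial) / sqrt(length(rep_b$per_trial))
  expect_lt(abs(mean(rep_b$per_trial) - 0.5), 2 * se + 0.02)

  pr_u <- classification_protocol("raw", "linear_svm", n_trials = 60,
                                  seed = 32)
  rep_u <- monte_carlo_classification(d$features, d$meta, pr_u)
  # majority-class rows dominate: true-b diagonal far above true-a diagonal
  expect_gt(rep_u$matrix["b", "b"], rep_u$matrix["a", "a"])
})

test_that("stable-pair features beat PCA-10 when the contrast lives in few pairs", {
  d <- separable_runs(n_subj_a = 10, n_subj_b = 10, n_feat = 60,
                      n_shifted = 3, effect = 1, seed = 41)
  pr_pca <- classification_protocol("pca10", "lda", n_trials = 30, seed = 51)
  acc_pca <- monte_carlo_classification(d$features, d$meta, pr_pca)$overall_accuracy
  pr_w <- classification_protocol("wilks_top10_stable", "lda", n_trials = 30,
                                  seed = 51)
  mc <- monte_carlo_stability(d$features, d$meta$group, d$meta$subject_id,
                              n_trials = 100, top_k = 10, seed = 52)
  stable <- select_stable(mc$counts, 10)
  acc_w <- monte_carlo_classification(d$features, d$meta, pr_w,
                                      pairs = stable)$overall_accuracy
  expect_gt(acc_w, acc_pca)
})

test_that("whole-data Wilks mode warns about double dipping", {
  d <- separable_runs(effect = 1, seed = 61)
  pr <- classification_protocol("wilks_top20_whole", "lda", n_trials = 3,
                                seed = 62)
  expect_warning(monte_carlo_classification(d$features, d$meta, pr),
                 "double dipping")
})

test_that("confusion report reproduces the class-size-weighted accuracy convention", {
  # printed per-class rates with groups of 15 and 32
  r1 <- report_confusion(rbind(c(26.73, 73.27), c(19.38, 80.63)),
                         class_sizes = c(15, 32))
  expect_equal(r1$overall_accuracy, 63.43, tolerance = 0.005)
  r2 <- report_confusion(rbind(c(50.47, 49.53), c(25.20, 74.80)),
                         class_sizes = c(15, 32))
  expect_equal(r2$overall_accuracy, 67.03, tolerance = 0.005)
  # perfect predictions
  r3 <- report_confusion(rbind(c(100, 0), c(0, 100)), c(10, 20))
  expect_equal(r3$overall_accuracy, 100)
  # raw counts normalised internally
  r4 <- report_confusion(rbind(c(3, 1), c(2, 6)), c(4, 8))
  expect_equal(unname(r4$matrix[1, ]), c(75, 25))
})

test_that("accuracy under label permutation stays near 50%", {
  d <- separable_runs(n_subj_a = 8, n_subj_b = 8, effect = 2, seed = 71)
  set.seed(72)
  accs <- vapply(1:40, function(i) {
    subj <- unique(d$meta$subject_id)
    relab <- setNames(sample(d$meta$group[match(subj, d$meta$subject_id)]),
                      subj)
    meta_p <- d$meta
    meta_p$group <- unname(relab[meta_p$subject_id])
    sp <- split_half(meta_p, seed = i)
    pred <- fit_predict("lda", d$features[sp$train, ], meta_p$group[sp$train],
                        d$features[sp$test, ])
    mean(pred == meta_p$group[sp$test])
  }, 0)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.03)
})
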